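#' Parameters of the two-scaffold-component growth model
#'
#' Centrosomes built from two scaffold formers plus an enzyme: component a
#' (a Spd-2/SPD-2-like recruiter) binds the PCM directly with a
#' size-dependent positive feedback, activates the enzyme E inside the
#' scaffold, and recruits component b (a Cnn/SPD-5-like bulk component) in a
#' loosely bound intermediate form b_i; the activated enzyme E* converts
#' intermediates into stably incorporated b-scaffold via an activated
#' complex E*b_i, releasing inactive enzyme. Two enzyme topologies are
#' supported: `"shared"` (E* joins one cytoplasmic pool serving both
#' centrosomes) and `"localized"` (E* made at centrosome i only acts at
#' centrosome i) - the only difference between the modes.
#'
#' @param rho_a,rho_b,rho_E Total concentrations of a, b and E (uM).
#' @param ka_plus,ka_minus a-scaffold assembly (uM^-1 s^-1) and disassembly
#'   (s^-1). Assembly has two channels: a centriole-anchored,
#'   size-independent channel at `ka_plus * [A] * s0`, and a PCM-distributed
#'   channel at `ka1_plus * [A] * (Sa_i + Sb_i)` that carries the
#'   size-dependent positive feedback (b strengthening the a-scaffold).
#' @param kb0_plus,kb0_minus Intermediate b binding (uM^-1 s^-1, a-dependent)
#'   and fall-off (s^-1).
#' @param kaE_plus Enzyme activation by scaffold a (uM^-1 s^-1).
#' @param kEb_plus E*-intermediate association (uM^-1 s^-1).
#' @param kb1_plus Incorporation of E*b_i into the b-scaffold. Quoted in
#'   bimolecular units in the source tables but the step is unimolecular;
#'   normalized by the 1 uM reference concentration to a pseudo-first-order
#'   rate (s^-1, numerically equal).
#' @param kb1_minus b-scaffold disassembly (s^-1).
#' @param Vc Cell volume (um^3).
#' @param delta_v Subunit volume (um^3; shared by a and b).
#' @param units A [unit_system()] or convention name.
#' @param enzyme_mode `"shared"` or `"localized"`.
#' @param ka1_plus PCM-distributed a-recruitment rate constant
#'   (uM^-1 s^-1 per scaffold subunit); the strength of the size-dependent
#'   positive feedback.
#' @param s0 Centriole-anchored assembly capacity in subunit-equivalents of
#'   1 uM x um^3 (so the channel contributes `s0 * c` effective anchored
#'   sites under count factor `c`; about 600 molecular sites at physical
#'   counts for the default 1). Keeps the pair dynamics invariant across
#'   count conventions and prevents an absorbing empty state.
#' @return A list of class `two_component_params`.
#' @export
two_component_params <- function(rho_a, rho_b, rho_E,
                                 ka_plus = 10, ka_minus = 5e-3,
                                 kb0_plus = 0.5, kb0_minus = 0.01,
                                 kaE_plus = 5e3, kEb_plus = 1e3,
                                 kb1_plus = 1e4, kb1_minus = 5e-3,
                                 ka1_plus = 3e-3,
                                 Vc = fixed_params()$Vc,
                                 delta_v = fixed_params()$delta_v,
                                 units = unit_system(),
                                 enzyme_mode = c("shared", "localized"),
                                 s0 = 1) {
  enzyme_mode <- match.arg(enzyme_mode)
  units <- as_unit_system(units)
  rates <- c(ka_plus, ka_minus, kb0_plus, kb0_minus, kaE_plus, kEb_plus,
             kb1_plus, kb1_minus, ka1_plus)
  stopifnot(all(rates >= 0), rho_a >= 0, rho_b >= 0, rho_E >= 0, Vc > 0,
            delta_v > 0, s0 >= 0)
  structure(list(rho_a = rho_a, rho_b = rho_b, rho_E = rho_E,
                 ka_plus = ka_plus, ka_minus = ka_minus,
                 ka1_plus = ka1_plus,
                 kb0_plus = kb0_plus, kb0_minus = kb0_minus,
                 kaE_plus = kaE_plus, kEb_plus = kEb_plus,
                 kb1_plus = kb1_plus, kb1_minus = kb1_minus,
                 Na = concentration_to_count(rho_a, Vc, units),
                 Nb = concentration_to_count(rho_b, Vc, units),
                 NE = concentration_to_count(rho_E, Vc, units),
                 Vc = Vc, delta_v = delta_v, units = units,
                 enzyme_mode = enzyme_mode, s0 = s0),
            class = "two_component_params")
}

#' Reaction network of the two-component model
#'
#' Species per centrosome i: `Sa_i` (a-scaffold), `bi_i` (loose b
#' intermediate), `Ebi_i` (activated intermediate), `Sb_i` (b-scaffold);
#' cytoplasm: `A`, `B`, `E`, and either a shared `Es` or per-centrosome
#' `Es1`, `Es2` (localized mode). Reactions per centrosome i:
#' \itemize{
#'   \item A1a `A -> Sa_i` at `ka+ (s0 c) [A]` (centriole-anchored,
#'     size-independent; `c` the count conversion factor);
#'   \item A1b `A -> Sa_i` at `ka1+ [A] (Sa_i + Sb_i)` (PCM-distributed,
#'     the size-dependent positive feedback);
#'   \item A2 `Sa_i -> A` at `ka- Sa_i`;
#'   \item B1 `B -> bi_i` at `kb0+ [B] Sa_i` (a-dependent binding);
#'   \item B2 `bi_i -> B` at `kb0- bi_i` (rapid fall-off);
#'   \item E1 `E -> E*` at `kaE+ [E] Sa_i`, the product entering the shared
#'     or the centrosome-local pool;
#'   \item E2 `E* + bi_i -> E*b_i` at `kEb+ [E*] bi_i` (localized mode uses
#'     only the local E*);
#'   \item B3 `E*b_i -> Sb_i + E` at `kb1+` (pseudo-first-order). In shared
#'     mode the enzyme is released inactive into the cytoplasm and must be
#'     re-activated by a PCM scaffold; in localized mode the enzyme stays
#'     anchored at its centrosome and is returned to the local active pool
#'     (the anchored-kinase picture), so enzyme captured by a centrosome
#'     keeps catalyzing that centrosome only;
#'   \item B4 `Sb_i -> B` at `kb1- Sb_i`.
#' }
#' Conserved sums: `A + Sa_1 + Sa_2 = N_a`,
#' `B + sum(bi + Ebi + Sb) = N_b`, `E + E*(+ E*_i) + sum(Ebi) = N_E`.
#'
#' @param params A [two_component_params()].
#' @param n_init Integer `c(Sa1, Sa2)` initial a-scaffold counts (the
#'   imposed initial size difference lives in the a-scaffold seeds).
#' @return A [reaction_network()].
#' @export
build_two_component_network <- function(params, n_init = c(25L, 25L)) {
  stopifnot(length(n_init) == 2L, all(n_init >= 0), sum(n_init) <= params$Na)
  cVc <- params$units$count_per_uM_um3 * params$Vc
  localized <- params$enzyme_mode == "localized"
  es_of <- function(i) if (localized) paste0("Es", i) else "Es"
  reactions <- list()
  for (i in 1:2) {
    Sa <- paste0("Sa", i); bi <- paste0("bi", i)
    Ebi <- paste0("Ebi", i); Sb <- paste0("Sb", i); Es <- es_of(i)
    reactions <- c(reactions, list(
      reaction(paste0("a_assembly_centriolar_", i),
               setNames(c(+1, -1), c(Sa, "A")),
               rate_spec(params$ka_plus * params$s0 *
                           params$units$count_per_uM_um3,
                         affine("A"), div = cVc)),
      reaction(paste0("a_assembly_distributed_", i),
               setNames(c(+1, -1), c(Sa, "A")),
               rate_spec(params$ka1_plus, affine("A"),
                         affine(c(Sa, Sb)), div = cVc)),
      reaction(paste0("a_disassembly_", i),
               setNames(c(-1, +1), c(Sa, "A")),
               rate_spec(params$ka_minus, affine(Sa))),
      reaction(paste0("b_bind_", i),
               setNames(c(+1, -1), c(bi, "B")),
               rate_spec(params$kb0_plus, affine("B"), affine(Sa),
                         div = cVc)),
      reaction(paste0("b_falloff_", i),
               setNames(c(-1, +1), c(bi, "B")),
               rate_spec(params$kb0_minus, affine(bi))),
      reaction(paste0("E_activation_", i),
               setNames(c(-1, +1), c("E", Es)),
               rate_spec(params$kaE_plus, affine("E"), affine(Sa),
                         div = cVc)),
      reaction(paste0("Eb_association_", i),
               setNames(c(-1, -1, +1), c(Es, bi, Ebi)),
               rate_spec(params$kEb_plus, affine(Es), affine(bi),
                         div = cVc)),
      reaction(paste0("b_incorporation_", i),
               if (localized) setNames(c(-1, +1, +1), c(Ebi, Sb, Es))
               else setNames(c(-1, +1, +1), c(Ebi, Sb, "E")),
               rate_spec(params$kb1_plus, affine(Ebi))),
      reaction(paste0("b_disassembly_", i),
               setNames(c(-1, +1), c(Sb, "B")),
               rate_spec(params$kb1_minus, affine(Sb)))
    ))
  }
  percent <- function(stub) paste0(stub, 1:2)
  species <- c(percent("Sa"), percent("bi"), percent("Ebi"), percent("Sb"),
               "A", "B", "E", if (localized) c("Es1", "Es2") else "Es")
  init <- setNames(numeric(length(species)), species)
  init[c("Sa1", "Sa2")] <- n_init
  init["A"] <- params$Na - sum(n_init)
  init["B"] <- params$Nb
  init["E"] <- params$NE
  es_names <- if (localized) c("Es1", "Es2") else "Es"
  conserved <- list(
    list(coef = c(A = 1, Sa1 = 1, Sa2 = 1), total = params$Na),
    list(coef = c(B = 1, bi1 = 1, bi2 = 1, Ebi1 = 1, Ebi2 = 1,
                  Sb1 = 1, Sb2 = 1), total = params$Nb),
    list(coef = setNames(rep(1, 3 + length(es_names)),
                         c("E", "Ebi1", "Ebi2", es_names)),
         total = params$NE))
  dv <- params$delta_v
  reaction_network(
    species = species, initial_state = init, reactions = reactions,
    conserved = conserved,
    meta = list(
      params = params[setdiff(names(params), "units")],
      model = "two_component",
      derived = list(
        V1 = function(s) (s[, "Sa1"] + s[, "Sb1"]) * dv,
        V2 = function(s) (s[, "Sa2"] + s[, "Sb2"]) * dv,
        Es_conc = if (localized)
          function(s) (s[, "Es1"] + s[, "Es2"]) / cVc
        else
          function(s) s[, "Es"] / cVc))
  )
}

#' Radial spread of the two scaffold components
#'
#' Converts scaffold subunit counts into equivalent-sphere radii,
#' `R = (3 V / 4 pi)^(1/3)`. The a-scaffold radius uses the a volume only;
#' the b radius uses the total scaffold volume (the b component envelops
#' the a core), so `R_b / R_a = ((Va + Vb) / Va)^(1/3)`.
#'
#' @param Sa,Sb Subunit counts of the a- and b-scaffold (vectors allowed).
#' @param delta_v Subunit volume (um^3).
#' @return List with `R_a` and `R_b` (um).
#' @export
radial_spread <- function(Sa, Sb, delta_v = fixed_params()$delta_v) {
  if (any(Sa < 0) || any(Sb < 0)) stop("counts must be non-negative")
  r <- function(v) (3 * v / (4 * pi))^(1 / 3)
  list(R_a = r(Sa * delta_v), R_b = r((Sa + Sb) * delta_v))
}
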