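#' Parameters of the autocatalytic (one-component) growth model
#'
#' Growth of a centrosome pair by stochastic assembly/disassembly of a
#' single subunit species from a shared limiting pool, with a
#' size-independent ("centriole activity") assembly term k0+ and a
#' size-proportional (cooperative, autocatalytic) term k1+. The
#' deterministic law per centrosome is
#' `dn_i/dt = (k0+ + k1+ n_i) rho(t) - k- n_i`, with
#' `rho(t) = (N - n1 - n2) / Vc` the free cytoplasmic subunit concentration.
#'
#' @param k0_plus Non-cooperative assembly rate constant (uM^-1 s^-1).
#' @param k1_plus Cooperative assembly rate constant (uM^-1 s^-1).
#' @param k_minus Disassembly rate constant (s^-1).
#' @param N Total subunit count; give either `N` or `rho0`.
#' @param rho0 Total subunit concentration (uM), converted to `N` via the
#'   unit convention.
#' @param Vc Cell volume (um^3).
#' @param delta_v Subunit volume (um^3).
#' @param units A [unit_system()] or convention name.
#' @param dk0_plus Centriole-activity excess of centrosome 1: the pair grows
#'   with `(k0+ + dk0+, k0+)`.
#' @param off_literal If `TRUE`, use the size-independent disassembly
#'   propensity `k-` (one subunit lost per event regardless of size) instead
#'   of the per-subunit form `k- * n_i`. The per-subunit form is the default
#'   because its mean field recovers the deterministic growth law.
#' @return A list of class `autocatalytic_params`.
#' @export
autocatalytic_params <- function(k0_plus, k1_plus, k_minus = fixed_params()$k_minus,
                                 N = NULL, rho0 = NULL,
                                 Vc = fixed_params()$Vc,
                                 delta_v = fixed_params()$delta_v,
                                 units = unit_system(), dk0_plus = 0,
                                 off_literal = FALSE) {
  units <- as_unit_system(units)
  if (is.null(N)) {
    if (is.null(rho0)) stop("give either N or rho0")
    N <- concentration_to_count(rho0, Vc, units)
  }
  stopifnot(k0_plus >= 0, k1_plus >= 0, k_minus >= 0, N >= 0, Vc > 0,
            delta_v > 0, dk0_plus >= 0)
  structure(list(k0_plus = k0_plus, k1_plus = k1_plus, k_minus = k_minus,
                 N = N, Vc = Vc, delta_v = delta_v, units = units,
                 dk0_plus = dk0_plus, off_literal = off_literal),
            class = "autocatalytic_params")
}

#' Deterministic growth law of the autocatalytic pair model
#'
#' Right-hand side `(dn1/dt, dn2/dt)` of the pair growth equations at a
#' given state, under the pinned unit convention (the bimolecular terms are
#' normalized by `c * Vc` so that `n` are molecule counts).
#'
#' @param state Numeric `c(n1, n2)`, non-negative, with `n1 + n2 <= N`.
#' @param params An [autocatalytic_params()].
#' @return Numeric `c(dn1, dn2)` in counts/s.
#' @export
autocatalytic_rhs <- function(state, params) {
  n1 <- state[[1]]; n2 <- state[[2]]
  if (n1 < 0 || n2 < 0 || n1 + n2 > params$N)
    stop("state outside the simplex 0 <= n1, n2, n1+n2 <= N")
  cVc <- params$units$count_per_uM_um3 * params$Vc
  rho <- (params$N - n1 - n2) / cVc   # uM
  k0 <- c(params$k0_plus + params$dk0_plus, params$k0_plus)
  d <- (k0 + params$k1_plus * c(n1, n2)) * rho - params$k_minus * c(n1, n2)
  unname(d)
}

#' Reaction network of the autocatalytic pair model
#'
#' Species: `n1`, `n2` (incorporated subunits) and `free` (cytoplasmic
#' pool). Per centrosome: a non-cooperative assembly channel with propensity
#' `k0+ * [free]`, a cooperative channel `k1+ * n_i * [free]` and
#' disassembly `k- * n_i` (per-subunit; see `off_literal` in
#' [autocatalytic_params()]). The subunit total `n1 + n2 + free = N` is a
#' declared conserved sum, held exactly along stochastic paths.
#'
#' @param params An [autocatalytic_params()].
#' @param n_init Integer `c(n1, n2)` initial incorporated counts.
#' @return A [reaction_network()].
#' @export
build_autocatalytic_network <- function(params, n_init = c(25L, 25L)) {
  stopifnot(length(n_init) == 2L, all(n_init >= 0),
            sum(n_init) <= params$N)
  cVc <- params$units$count_per_uM_um3 * params$Vc
  k0 <- c(params$k0_plus + params$dk0_plus, params$k0_plus)
  reactions <- list()
  for (i in 1:2) {
    ni <- paste0("n", i)
    reactions <- c(reactions, list(
      reaction(paste0("assembly0_", i),
               setNames(c(+1, -1), c(ni, "free")),
               rate_spec(k0[i], affine("free"), div = cVc)),
      reaction(paste0("assembly1_", i),
               setNames(c(+1, -1), c(ni, "free")),
               rate_spec(params$k1_plus, affine(ni), affine("free"),
                         div = cVc)),
      reaction(paste0("disassembly_", i),
               setNames(c(-1, +1), c(ni, "free")),
               if (params$off_literal)
                 rate_spec(params$k_minus, affine(const = 1))
               else
                 rate_spec(params$k_minus, affine(ni)))
    ))
  }
  dv <- params$delta_v
  reaction_network(
    species = c("n1", "n2", "free"),
    initial_state = c(n1 = n_init[1], n2 = n_init[2],
                      free = params$N - sum(n_init)),
    reactions = reactions,
    conserved = list(list(coef = c(n1 = 1, n2 = 1, free = 1),
                          total = params$N)),
    meta = list(
      params = params[c("k0_plus", "k1_plus", "k_minus", "N", "Vc",
                        "delta_v", "dk0_plus")],
      model = "autocatalytic",
      derived = list(
        V1 = function(s) s[, "n1"] * dv,
        V2 = function(s) s[, "n2"] * dv))
  )
}

#' Steady-state volume of the non-cooperative limit
#'
#' In the non-cooperative limit (k1+ = 0) the pair model has the closed-form
#' symmetric steady state `V = k+ N delta_v / (k- + 2 k+)`, where `k+` and
#' `k-` must be expressed in the same per-time units; here `k-` (s^-1) is
#' converted to the bimolecular scale via the `c * Vc` normalization used in
#' the propensities.
#'
#' @param k_plus Assembly rate constant (uM^-1 s^-1).
#' @param N Total subunit count.
#' @param k_minus Disassembly rate constant (s^-1).
#' @param Vc Cell volume (um^3).
#' @param delta_v Subunit volume (um^3).
#' @param units A [unit_system()] or convention name.
#' @return Steady-state per-centrosome volume (um^3).
#' @export
noncooperative_steady_volume <- function(k_plus, N,
                                         k_minus = fixed_params()$k_minus,
                                         Vc = fixed_params()$Vc,
                                         delta_v = fixed_params()$delta_v,
                                         units = unit_system()) {
  units <- as_unit_system(units)
  if (k_plus == 0 && k_minus == 0)
    stop("k_plus and k_minus cannot both be zero")
  k_minus_eff <- k_minus * units$count_per_uM_um3 * Vc  # uM^-1 s^-1 scale
  k_plus * N * delta_v / (k_minus_eff + 2 * k_plus)
}

#' Size-equality condition of the autocatalytic pair model
#'
#' Linearization of the pair growth law about the symmetric steady state
#' shows the size difference decays iff `2 k0+ + k- Vc > k1+ N`, where all
#' three terms are expressed on the same bimolecular scale: `k- Vc` enters
#' as `k- * (c * Vc)` and `k1+ N` as printed, with `c` the count conversion
#' factor. `TRUE` predicts ensemble size equality; `FALSE` predicts
#' amplification of any initial size difference.
#'
#' @param params An [autocatalytic_params()].
#' @return Logical.
#' @export
equality_condition_holds <- function(params) {
  cVc <- params$units$count_per_uM_um3 * params$Vc
  2 * params$k0_plus + params$k_minus * cVc > params$k1_plus * params$N
}
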