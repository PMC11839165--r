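#' Parameters of the single-component catalytic growth model
#'
#' PCM growth catalyzed by a shared enzyme: inactive subunits S1 assemble
#' slowly (rate `k+`, the centriole-localized activity), enzyme E is
#' activated inside the PCM at a size-proportional rate (`kE*`), the
#' activated enzyme E* converts free subunits to an activated form S1* in
#' the cytoplasm (`k1*`), and activated subunits assemble fast (`k*`). The
#' positive feedback (bigger PCM -> more E* -> faster growth) is routed
#' through the shared cytoplasmic pool, not through each centrosome
#' privately. Pools are limiting: `S1 = N - Sn,1 - Sn,2 - S1*` and
#' `E = N_E - E* - S1*` (an activated subunit carries one enzyme, which is
#' released inactive upon incorporation).
#'
#' @param k_plus Inactive-subunit assembly rate constant (uM^-1 s^-1),
#'   per centrosome; centrosome 1 uses `k_plus + dk_plus`.
#' @param k_star Active-subunit assembly rate constant (uM^-1 s^-1).
#' @param k1_star Enzyme-dependent subunit activation rate constant
#'   (uM^-1 s^-1).
#' @param kE_star PCM-dependent enzyme activation rate constant. Quoted
#'   per-subunit per-uM of inactive enzyme (numerically the tabulated s^-1
#'   value); the propensity is `kE* * Sn_i * [E]`.
#' @param k_minus Disassembly rate constant (s^-1).
#' @param rho0 Total subunit concentration (uM).
#' @param E_conc Total enzyme concentration (uM); in `unlimited_pool` mode
#'   the concentration at which inactive enzyme is clamped.
#' @param Vc Cell volume (um^3).
#' @param delta_v Subunit volume (um^3).
#' @param units A [unit_system()] or convention name.
#' @param enzyme_mode `"limited_pool"` (E conserved) or `"unlimited_pool"`
#'   (inactive-enzyme concentration held constant, no E bookkeeping).
#' @param dk_plus Centriolar-activity excess of centrosome 1 (uM^-1 s^-1).
#' @return A list of class `catalytic_params`.
#' @export
catalytic_params <- function(k_plus, k_star, k1_star, kE_star,
                             k_minus = fixed_params()$k_minus,
                             rho0, E_conc,
                             Vc = fixed_params()$Vc,
                             delta_v = fixed_params()$delta_v,
                             units = unit_system(),
                             enzyme_mode = c("limited_pool", "unlimited_pool"),
                             dk_plus = 0) {
  enzyme_mode <- match.arg(enzyme_mode)
  units <- as_unit_system(units)
  stopifnot(k_plus >= 0, k_star >= 0, k1_star >= 0, kE_star >= 0,
            k_minus >= 0, rho0 >= 0, E_conc >= 0, Vc > 0, delta_v > 0,
            dk_plus >= 0)
  N <- concentration_to_count(rho0, Vc, units)
  NE <- concentration_to_count(E_conc, Vc, units)
  structure(list(k_plus = k_plus, k_star = k_star, k1_star = k1_star,
                 kE_star = kE_star, k_minus = k_minus, rho0 = rho0,
                 E_conc = E_conc, N = N, NE = NE, Vc = Vc,
                 delta_v = delta_v, units = units,
                 enzyme_mode = enzyme_mode, dk_plus = dk_plus),
            class = "catalytic_params")
}

#' Deterministic growth law of the catalytic pair model
#'
#' Time derivatives of the pair state `(Sn1, Sn2, S1s, Es)` (incorporated
#' subunits per centrosome, free activated subunits, free activated
#' enzymes), with the free inactive pools obtained from the conservation
#' constraints. All states are molecule counts; bimolecular terms are
#' normalized by `c * Vc`.
#'
#' @param state Named or positional numeric `c(Sn1, Sn2, S1s, Es)`.
#' @param params A [catalytic_params()].
#' @return Numeric `c(dSn1, dSn2, dS1s, dEs)` in counts/s.
#' @export
catalytic_rhs <- function(state, params) {
  Sn1 <- state[[1]]; Sn2 <- state[[2]]; S1s <- state[[3]]; Es <- state[[4]]
  cVc <- params$units$count_per_uM_um3 * params$Vc
  S1 <- params$N - Sn1 - Sn2 - S1s
  if (min(Sn1, Sn2, S1s, Es, S1) < -1e-9)
    stop("state violates the pool constraints")
  kp <- c(params$k_plus + params$dk_plus, params$k_plus)
  assembly <- kp * S1 / cVc + params$k_star * S1s / cVc
  dSn <- assembly - params$k_minus * c(Sn1, Sn2)
  activation <- params$k1_star * S1 * Es / cVc
  dS1s <- activation - 2 * params$k_star * S1s / cVc
  E_term <- if (params$enzyme_mode == "limited_pool") {
    E <- params$NE - Es - S1s
    if (E < -1e-9) stop("state violates the enzyme constraint")
    params$kE_star * (Sn1 + Sn2) * E / cVc
  } else {
    params$kE_star * (Sn1 + Sn2) * params$E_conc
  }
  dEs <- E_term - activation
  unname(c(dSn, dS1s, dEs))
}

#' Reaction network of the catalytic pair model
#'
#' Implements the catalytic reaction scheme for a centrosome pair sharing
#' both pools. Per centrosome i:
#' \itemize{
#'   \item R1: `S1 + C_i -> C_i+1` at `k+_i [S1]` (centriole-localized,
#'     size-independent);
#'   \item R2: `S1* + C_i -> C_i+1 + E` at `k* [S1*]` (the enzyme carried by
#'     the activated subunit is released inactive, enforcing enzyme
#'     conservation);
#'   \item R3: `E -> E*` at `kE* Sn_i [E]` (activation inside the PCM,
#'     proportional to PCM size);
#'   \item R4: `S1 + E* -> S1*` at `k1* [S1] [E*] c Vc` (cytoplasmic,
#'     shared);
#'   \item R5: `C_i -> C_i-1 + S1` at `k- Sn_i` (distributed turnover,
#'     returning inactive subunits).
#' }
#' In `unlimited_pool` mode R3 uses the clamped concentration `E_conc` and
#' no inactive-enzyme species is tracked.
#'
#' @param params A [catalytic_params()].
#' @param n_init Integer initial incorporated counts, one per centrosome
#'   (length 1 or 2; a single-centrosome network is used for closed-form
#'   cross-checks and size-scaling sweeps).
#' @return A [reaction_network()] with conserved sums N (and N_E in limited
#'   mode).
#' @export
build_catalytic_network <- function(params, n_init = c(25L, 25L)) {
  M <- length(n_init)
  stopifnot(M %in% 1:2, all(n_init >= 0), sum(n_init) <= params$N)
  cVc <- params$units$count_per_uM_um3 * params$Vc
  limited <- params$enzyme_mode == "limited_pool"
  kp <- c(params$k_plus + params$dk_plus, params$k_plus)
  if (M == 1L) kp <- params$k_plus
  reactions <- list()
  for (i in seq_len(M)) {
    Sni <- paste0("Sn", i)
    reactions <- c(reactions, list(
      reaction(paste0("assemble_inactive_", i),
               setNames(c(+1, -1), c(Sni, "S1")),
               rate_spec(kp[i], affine("S1"), div = cVc)),
      reaction(paste0("assemble_active_", i),
               if (limited) setNames(c(+1, -1, +1), c(Sni, "S1s", "E"))
               else setNames(c(+1, -1), c(Sni, "S1s")),
               rate_spec(params$k_star, affine("S1s"), div = cVc)),
      if (limited)
        reaction(paste0("activate_enzyme_", i),
                 c(E = -1, Es = +1),
                 rate_spec(params$kE_star, affine(Sni), affine("E"),
                           div = cVc))
      else
        reaction(paste0("activate_enzyme_", i),
                 c(Es = +1),
                 rate_spec(params$kE_star * params$E_conc, affine(Sni))),
      reaction(paste0("disassemble_", i),
               setNames(c(-1, +1), c(Sni, "S1")),
               rate_spec(params$k_minus, affine(Sni)))
    ))
  }
  reactions <- c(reactions, list(
    reaction("activate_subunit",
             c(S1 = -1, Es = -1, S1s = +1),
             rate_spec(params$k1_star, affine("S1"), affine("Es"),
                       div = cVc))))
  sn_names <- paste0("Sn", seq_len(M))
  species <- c(sn_names, "S1", "S1s", if (limited) "E", "Es")
  init <- c(setNames(n_init, sn_names),
            S1 = params$N - sum(n_init), S1s = 0,
            if (limited) c(E = params$NE), Es = 0)
  names(init) <- species
  conserved <- list(list(coef = setNames(rep(1, M + 2), c(sn_names, "S1", "S1s")),
                         total = params$N))
  if (limited)
    conserved <- c(conserved,
                   list(list(coef = c(E = 1, Es = 1, S1s = 1),
                             total = params$NE)))
  dv <- params$delta_v
  derived <- list(V1 = function(s) s[, "Sn1"] * dv)
  if (M == 2L) derived$V2 <- function(s) s[, "Sn2"] * dv
  derived$Es_conc <- function(s) s[, "Es"] / cVc
  reaction_network(
    species = species, initial_state = init, reactions = reactions,
    conserved = conserved,
    meta = list(
      params = params[c("k_plus", "k_star", "k1_star", "kE_star", "k_minus",
                        "rho0", "E_conc", "N", "NE", "Vc", "delta_v",
                        "enzyme_mode", "dk_plus")],
      model = "catalytic",
      derived = derived)
  )
}

#' Closed-form steady-state volume of a single catalytic centrosome
#'
#' Assuming the activated enzyme settles fast to an abundance `E*`, the
#' steady-state volume of a single centrosome is
#' \deqn{V = \frac{(E^* k_1^* + k^+)\, k^* \rho_0 V_c \delta v}
#'            {k^*(k^+ + k^- V_c) + E^* k_1^* (k^* + k^- V_c)},}
#' with `k- Vc` entering on the bimolecular scale (`k- * c * Vc`) and
#' `rho0 Vc` as the total subunit count (`rho0 * c * Vc`); `E*` is a
#' molecule count. With `solve_E_star = TRUE` (limited pool) `E*` is found
#' self-consistently from the enzyme balance at steady state before
#' substitution.
#'
#' @param params A [catalytic_params()].
#' @param E_star_ss Steady-state activated-enzyme count; required unless
#'   `solve_E_star = TRUE`.
#' @param solve_E_star Solve for `E*` from the enzyme balance (limited
#'   mode).
#' @return Steady-state volume (um^3).
#' @export
steady_state_volume <- function(params, E_star_ss = NULL,
                                solve_E_star = is.null(E_star_ss)) {
  cVc <- params$units$count_per_uM_um3 * params$Vc
  km_eff <- params$k_minus * cVc
  ks <- params$k_star; kp <- params$k_plus; k1s <- params$k1_star
  vol_of_Es <- function(Es) {
    den <- ks * (kp + km_eff) + Es * k1s * (ks + km_eff)
    if (den <= 0) stop("zero denominator in steady-state volume")
    (Es * k1s + kp) * ks * params$rho0 * cVc * params$delta_v / den
  }
  if (solve_E_star) {
    if (params$enzyme_mode != "limited_pool")
      stop("solve_E_star requires the limited enzyme pool")
    balance <- function(Es) {
      V <- vol_of_Es(Es)
      Sn <- V / params$delta_v
      S1 <- km_eff * Sn / (kp + k1s * Es)
      S1s <- k1s * S1 * Es / ks
      E <- params$NE - Es - S1s
      params$kE_star * Sn * E / cVc - k1s * S1 * Es / cVc
    }
    lo <- 0; hi <- params$NE
    if (balance(lo) <= 0) {
      E_star_ss <- 0
    } else {
      E_star_ss <- uniroot(balance, c(lo, hi), tol = 1e-10)$root
    }
  }
  vol_of_Es(E_star_ss)
}

#' Activation-pulse metrics of a time series
#'
#' The catalytic models predict a transient early maximum (an "activation
#' pulse") in the cytoplasmic activated-enzyme abundance. This helper
#' extracts the pulse amplitude (global maximum), peak time (argmax) and
#' lifetime, defined as the full width at half maximum with the crossing
#' times obtained by linear interpolation. A series whose maximum sits at
#' either boundary, or which is monotone, is reported as `pulse = FALSE`.
#'
#' @param trajectory A `trajectory`.
#' @param species Column to analyse, looked up among species counts and
#'   derived series (default the activated-enzyme count `"Es"`).
#' @return List with `pulse` (logical), `amplitude`, `peak_time`,
#'   `lifetime` (s; `NA` if the series never falls back to half maximum).
#' @export
pulse_metrics <- function(trajectory, species = "Es") {
  df <- as.data.frame(trajectory)
  if (!species %in% names(df))
    stop("series '", species, "' not found in trajectory")
  y <- df[[species]]; t <- df$time
  if (length(y) < 3L || all(!is.finite(y))) stop("series is empty")
  i_max <- which.max(y)
  amplitude <- y[i_max]
  monotone <- all(diff(y) >= 0) || all(diff(y) <= 0)
  if (i_max == 1L || i_max == length(y) || monotone || amplitude <= 0)
    return(list(pulse = FALSE, amplitude = amplitude,
                peak_time = t[i_max], lifetime = NA_real_))
  half <- amplitude / 2
  cross <- function(idx_range, rising) {
    yy <- y[idx_range]; tt <- t[idx_range]
    if (rising) {
      i <- max(which(yy < half))
      if (i == length(yy)) return(NA_real_)
      approx(yy[c(i, i + 1)], tt[c(i, i + 1)], xout = half)$y
    } else {
      below <- which(yy < half)
      if (!length(below)) return(NA_real_)
      i <- min(below)
      if (i == 1L) return(tt[1])
      approx(yy[c(i - 1, i)], tt[c(i - 1, i)], xout = half)$y
    }
  }
  t_up <- if (any(y[1:i_max] < half)) cross(1:i_max, TRUE) else NA_real_
  t_down <- cross(i_max:length(y), FALSE)
  list(pulse = TRUE, amplitude = amplitude, peak_time = t[i_max],
       lifetime = t_down - t_up)
}
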