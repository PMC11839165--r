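#' Fit a Hill function to a growth curve
#'
#' Quantifies the cooperativity of a growth trajectory by least-squares
#' fitting of `V(t) = A t^alpha / (B^alpha + t^alpha)`: `A` is the plateau
#' volume, `B` the half-rise time and `alpha` the Hill coefficient; growth
#' is called sigmoidal when `alpha >= 2`. The fit is deterministic given the
#' series: initialization is `A0 = max(V)`, `B0 =` time of half-maximum,
#' `alpha0 = 2`, and the optimizer is Levenberg-Marquardt.
#'
#' @param times Time grid (s), at least 8 points.
#' @param volumes Volume series (um^3), overall non-decreasing trend.
#' @return A list of class `hill_fit`: `A`, `B`, `alpha`, `rss`.
#' @export
fit_hill <- function(times, volumes) {
  stopifnot(length(times) == length(volumes))
  keep <- is.finite(times) & is.finite(volumes)
  times <- times[keep]; volumes <- volumes[keep]
  if (length(times) < 8L) stop("need at least 8 time points")
  if (tail(volumes, 1L) < head(volumes, 1L))
    stop("series has a decreasing overall trend; not a growth curve")
  A0 <- max(volumes)
  i_half <- which(volumes >= A0 / 2)[1]
  B0 <- if (is.na(i_half) || i_half == 1L) max(times) / 2 else times[i_half]
  B0 <- max(B0, min(times[times > 0]))
  df <- data.frame(t = times, V = volumes)
  fit <- tryCatch(
    minpack.lm::nlsLM(V ~ A * t^alpha / (B^alpha + t^alpha), data = df,
                      start = list(A = A0, B = B0, alpha = 2),
                      lower = c(A = 1e-12, B = 1e-12, alpha = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e),
                             " (A0=", signif(A0, 4), ", B0=", signif(B0, 4),
                             ")"))
  cf <- coef(fit)
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 alpha = unname(cf["alpha"]),
                 rss = sum(residuals(fit)^2), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit: A = %.4g um^3, B = %.4g s, alpha = %.3g (%ssigmoidal)>\n",
    x$A, x$B, x$alpha, if (x$alpha >= 2) "" else "non-"))
  invisible(x)
}

#' Steady-state readout time of a deterministic trajectory
#'
#' The declared readout time for "steady-state" quantities: the first grid
#' time at which the total centrosome volume changes by less than `frac`
#' (relative) per `window` seconds. Stochastic finals are read at the same
#' time as their deterministic twin.
#'
#' @param trajectory A `trajectory` with derived `V1`/`V2` series.
#' @param frac Relative-change threshold (default 0.1% = 1e-3).
#' @param window Comparison window (s, default 100).
#' @return Time in seconds (the trajectory end time, with a warning, if the
#'   criterion is never met).
#' @export
steady_readout_time <- function(trajectory, frac = 1e-3, window = 100) {
  df <- as.data.frame(trajectory)
  V <- df$V1 + if (!is.null(df$V2)) df$V2 else 0
  t <- df$time
  Vfun <- function(tt) approx(t, V, xout = tt, rule = 2)$y
  ok <- which(vapply(seq_along(t), function(i) {
    v0 <- V[i]; v1 <- Vfun(t[i] + window)
    v0 > 0 && abs(v1 - v0) / v0 < frac
  }, logical(1)))
  if (!length(ok)) {
    warning("steady-state criterion not met; using trajectory end time")
    return(max(t))
  }
  t[ok[1]]
}

state_at_time <- function(trajectory, t_read) {
  df <- as.data.frame(trajectory)
  i <- which.min(abs(df$time - t_read))
  df[i, , drop = FALSE]
}

#' Robustness of size equality to the initial size difference
#'
#' For each initial volume difference in `dV0_grid`, runs a stochastic
#' ensemble of centrosome pairs and records the final sizes at the readout
#' time; reports the ensemble mean relative absolute size difference
#' `mean(|V1 - V2|) / mean(V)` per grid point, the Pearson correlation
#' (with two-sided p-value) between the per-run initial difference (pooled
#' across the grid) and the signed final difference, and the linear
#' regression slope of the per-run relative difference on `dV0` with its
#' 95% confidence interval. A robust size-control mechanism shows a flat
#' profile and a correlation indistinguishable from zero; autocatalytic
#' amplification shows a positive correlation and a rising profile.
#'
#' @param network_factory Function `(dV0, seed) -> reaction_network` for a
#'   pair model whose trajectories expose derived `V1`, `V2`.
#' @param dV0_grid Initial volume differences (um^3).
#' @param n_runs Runs per grid point (>= 100 recommended for CI validity).
#' @param base_seed First seed; seeds advance across grid points and runs.
#' @param t_max Simulation end time (s).
#' @param t_read Readout time (s), default `t_max`.
#' @param ... Passed to [simulate_ssa()].
#' @return A list of class `robustness_result`.
#' @export
robustness_scan <- function(network_factory, dV0_grid, n_runs, base_seed = 1L,
                            t_max, t_read = t_max, ...) {
  per_run <- list()
  for (g in seq_along(dV0_grid)) {
    dV0 <- dV0_grid[g]
    seeds <- base_seed + (g - 1L) * n_runs + seq_len(n_runs) - 1L
    for (s in seeds) {
      tr <- simulate_ssa(network_factory(dV0, s), t_max = t_max, seed = s, ...)
      st <- state_at_time(tr, t_read)
      per_run[[length(per_run) + 1L]] <-
        data.frame(dV0 = dV0, seed = s, V1 = st$V1, V2 = st$V2)
    }
  }
  runs <- do.call(rbind, per_run)
  runs$dV <- runs$V1 - runs$V2
  meanV <- mean(c(runs$V1, runs$V2))
  prof <- vapply(split(runs, runs$dV0),
                 function(d) mean(abs(d$dV)) / mean(c(d$V1, d$V2)),
                 numeric(1))
  ct <- if (length(unique(runs$dV0)) > 1L)
    cor.test(runs$dV0, runs$dV, alternative = "two.sided")
  else list(estimate = NA_real_, p.value = NA_real_)
  runs$rel_abs <- abs(runs$dV) / meanV
  sl <- lm(rel_abs ~ dV0, data = runs)
  ci <- confint(sl)["dV0", ]
  structure(list(dV0_grid = sort(unique(runs$dV0)),
                 mean_abs_dV_over_meanV = prof[order(as.numeric(names(prof)))],
                 pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 slope = unname(coef(sl)["dV0"]), slope_ci = unname(ci),
                 n_runs = n_runs, t_read = t_read, runs = runs),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("<robustness_result>\n")
  cat("  mean |dV|/<V> per dV0:",
      paste(sprintf("%.3g", x$mean_abs_dV_over_meanV), collapse = ", "), "\n")
  cat(sprintf("  Pearson r(dV0, dV) = %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  cat(sprintf("  slope = %.3g [%.3g, %.3g] per um^3\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Efficiency of differential-growth size control
#'
#' In the differential-activity protocol, centrosome 1 carries the higher
#' centriole activity and starts *smaller* by `dV0` (deficit assignment).
#' The efficiency of asymmetry control is the fraction of stochastic runs
#' in which the higher-activity centrosome nevertheless ends up larger,
#' `epsilon = N+ / N_tot`; exact final-size ties count 1/2. A Wilson 95%
#' interval quantifies the ensemble uncertainty.
#'
#' @param network_factory Function `seed -> reaction_network` for a pair
#'   model already configured with the activity excess on centrosome 1 and
#'   the initial deficit.
#' @param n_runs Number of pairs simulated (>= 100 recommended).
#' @param base_seed First seed.
#' @param t_max Simulation end time (s).
#' @param t_read Readout time (s), default `t_max`.
#' @param ... Passed to [simulate_ssa()].
#' @return A list of class `efficiency_result`: `epsilon`, `n_plus`,
#'   `n_total`, `wilson_ci`.
#' @export
asymmetry_efficiency <- function(network_factory, n_runs, base_seed = 1L,
                                 t_max, t_read = t_max, ...) {
  stopifnot(n_runs >= 1)
  seeds <- base_seed + seq_len(n_runs) - 1L
  wins <- 0
  for (s in seeds) {
    tr <- simulate_ssa(network_factory(s), t_max = t_max, seed = s, ...)
    st <- state_at_time(tr, t_read)
    wins <- wins + if (st$V1 > st$V2) 1 else if (st$V1 == st$V2) 0.5 else 0
  }
  structure(list(epsilon = wins / n_runs, n_plus = wins, n_total = n_runs,
                 wilson_ci = wilson_ci(wins, n_runs)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result: epsilon = %.3f (%g/%d), 95%% CI [%.3f, %.3f]>\n",
              x$epsilon, x$n_plus, x$n_total,
              x$wilson_ci[1], x$wilson_ci[2]))
  invisible(x)
}

#' Centrosome size scaling with cell size
#'
#' Sweeps the cell volume at fixed total concentrations (the limiting-pool
#' rule: `N = rho0 * c * Vc`), integrates the deterministic pair model to
#' steady state for each `Vc`, and reports the per-centrosome steady-state
#' volume, the scaling slope `dV/dVc` (central differences; also in
#' `delta_v` units), and the residual cytoplasmic subunit fraction
#' `(S1 + S1*) / N`. Strong scaling (`V -> rho0 Vc delta_v` per pool share)
#' goes together with strong pool depletion; weak scaling leaves most of
#' the pool in the cytoplasm.
#'
#' @param params A [catalytic_params()]; its `Vc` is replaced by the grid
#'   values.
#' @param Vc_grid Increasing cell volumes (um^3).
#' @param t_max Integration horizon (s); runs not reaching steady state are
#'   flagged.
#' @param n_init Initial pair counts.
#' @return A list of class `scaling_result`.
#' @export
size_scaling_sweep <- function(params, Vc_grid, t_max = 2e4,
                               n_init = c(25L, 25L)) {
  stopifnot(!is.unsorted(Vc_grid), length(Vc_grid) >= 3L)
  V_ss <- depletion <- numeric(length(Vc_grid))
  steady <- logical(length(Vc_grid))
  for (i in seq_along(Vc_grid)) {
    p <- catalytic_params(
      k_plus = params$k_plus, k_star = params$k_star,
      k1_star = params$k1_star, kE_star = params$kE_star,
      k_minus = params$k_minus, rho0 = params$rho0, E_conc = params$E_conc,
      Vc = Vc_grid[i], delta_v = params$delta_v, units = params$units,
      enzyme_mode = params$enzyme_mode, dk_plus = params$dk_plus)
    tr <- simulate_ode(build_catalytic_network(p, n_init), t_max = t_max)
    df <- as.data.frame(tr)
    last <- df[nrow(df), ]
    prev <- df[nrow(df) - 10L, ]
    steady[i] <- abs(last$V1 - prev$V1) / max(last$V1, 1e-12) < 1e-3
    V_ss[i] <- last$V1
    depletion[i] <- (last$S1 + last$S1s) / p$N
  }
  if (!all(steady)) warning("non-steady runs at Vc = ",
                            paste(Vc_grid[!steady], collapse = ", "))
  slope <- rep(NA_real_, length(Vc_grid))
  inner <- 2:(length(Vc_grid) - 1L)
  slope[inner] <- (V_ss[inner + 1L] - V_ss[inner - 1L]) /
    (Vc_grid[inner + 1L] - Vc_grid[inner - 1L])
  slope[1] <- (V_ss[2] - V_ss[1]) / (Vc_grid[2] - Vc_grid[1])
  slope[length(slope)] <- (V_ss[length(V_ss)] - V_ss[length(V_ss) - 1L]) /
    (Vc_grid[length(V_ss)] - Vc_grid[length(V_ss) - 1L])
  structure(list(Vc_grid = Vc_grid, V_ss = V_ss, slope = slope,
                 slope_delta_v_units = slope / params$delta_v,
                 depletion_fraction = depletion, steady = as.logical(steady)),
            class = "scaling_result")
}

#' Stokes-Einstein diffusion constant from protein mass
#'
#' Cytosolic diffusion constants estimated by mass scaling,
#' `D = D_ref * (M_ref / M)^(1/3)` (protein radius scales as mass^(1/3)),
#' anchored at GFP: 30 um^2/s at 30 kDa.
#'
#' @param mass_kDa Protein mass (kDa), positive.
#' @param D_ref,M_ref Reference diffusion constant (um^2/s) and mass (kDa).
#' @return Diffusion constant (um^2/s).
#' @export
stokes_einstein_D <- function(mass_kDa, D_ref = 30, M_ref = 30) {
  if (any(mass_kDa <= 0)) stop("mass must be positive")
  D_ref * (M_ref / mass_kDa)^(1 / 3)
}

#' Diffusion timescale over a distance
#'
#' `tau_D = L^2 / (6 D)`, the three-dimensional diffusion time over a
#' distance `L`.
#'
#' @param L Distance (um), positive.
#' @param D Diffusion constant (um^2/s), positive.
#' @return Time in seconds.
#' @export
diffusion_time <- function(L, D) {
  if (any(L <= 0) || any(D <= 0)) stop("L and D must be positive")
  L^2 / (6 * D)
}
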