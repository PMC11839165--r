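new_trajectory <- function(times, states, network = NULL, meta = list(),
                           absorbed = FALSE) {
  states <- as.matrix(states)
  traj <- structure(list(times = times, states = states,
                         species = colnames(states), meta = meta,
                         absorbed = absorbed),
                    class = "trajectory")
  if (!is.null(network) && length(network$meta$derived)) {
    dv <- lapply(network$meta$derived, function(f) f(states))
    traj$derived <- as.data.frame(dv)
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d records over [0, %g] s; species: %s%s>\n",
              length(x$times), max(x$times),
              paste(x$species, collapse = ", "),
              if (isTRUE(x$absorbed)) "; absorbed" else ""))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  out <- data.frame(time = x$times, x$states, check.names = FALSE)
  if (!is.null(x$derived)) out <- cbind(out, x$derived)
  out
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates a [reaction_network()] with the direct method: the waiting time
#' to the next event is `tau = log(1/r1) / sum(a)` and the firing reaction is
#' chosen by inverting the cumulative propensity with a second uniform
#' variate `r2` (first index whose cumulative share exceeds `r2`). The
#' engine guarantees non-negative counts and stops with a diagnostic if any
#' propensity evaluates to a negative number or NaN.
#'
#' Networks whose reactions all carry [rate_spec()] propensities run in the
#' compiled core; networks with R-function propensities run in a plain-R
#' reference loop (identical algorithm, same RNG stream).
#'
#' @param network A [reaction_network()].
#' @param t_max End time (s), positive.
#' @param seed Integer seed; the same (network, seed) pair yields a
#'   bit-identical trajectory.
#' @param recording Either `"grid"` (default: `n_grid + 1` uniformly spaced
#'   records including t = 0, each holding the state just before the first
#'   event after that time) or `"every_event"`.
#' @param n_grid Number of grid intervals for `recording = "grid"`.
#' @param max_events Safety cap on the number of events.
#' @param engine `"auto"` (compiled when possible), `"compiled"`, or `"r"`.
#' @return A `trajectory` object: `times`, `states` (one row per record),
#'   optional model-defined derived series, and an `absorbed` flag set when
#'   all propensities vanished before `t_max`.
#' @export
simulate_ssa <- function(network, t_max, seed = 1L,
                         recording = c("grid", "every_event"), n_grid = 500L,
                         max_events = 5e8, engine = c("auto", "compiled", "r")) {
  recording <- match.arg(recording)
  engine <- match.arg(engine)
  stopifnot(t_max > 0)
  enc <- encode_network(network)
  use_compiled <- switch(engine,
    auto = !is.null(enc),
    compiled = { if (is.null(enc)) stop(
      "network has R-function propensities; compiled engine unavailable"); TRUE },
    r = FALSE)

  grid <- seq(0, t_max, length.out = n_grid + 1L)
  set.seed(seed)
  if (use_compiled) {
    res <- ssa_core(as.numeric(network$initial_state), enc$delta, enc$k,
                    enc$div, enc$f1, enc$f2, enc$names, t_max, grid,
                    recording == "every_event", max_events)
    if (recording == "every_event") {
      states <- res$event_states
      times <- res$event_times
    } else {
      states <- res$grid_states
      times <- grid
    }
    colnames(states) <- network$species
    meta <- c(network$meta["params"],
              list(seed = seed, t_max = t_max, n_events = res$n_events,
                   engine = "compiled"))
    return(new_trajectory(times, states, network, meta,
                          absorbed = res$absorbed))
  }
  simulate_ssa_r(network, t_max, grid, recording, max_events, seed)
}

# reference R implementation of the identical direct-method loop
simulate_ssa_r <- function(network, t_max, grid, recording, max_events, seed) {
  x <- network$initial_state
  D <- delta_matrix(network)
  t <- 0; gi <- 1L; n_events <- 0; absorbed <- FALSE
  G <- length(grid)
  grid_states <- matrix(NA_real_, G, length(x),
                        dimnames = list(NULL, network$species))
  ev_t <- list(); ev_x <- list()
  if (recording == "every_event") { ev_t[[1]] <- 0; ev_x[[1]] <- x }
  repeat {
    a <- eval_propensities(network, x, t)
    if (any(is.nan(a) | a < 0)) {
      j <- which(is.nan(a) | a < 0)[1]
      stop("propensity of reaction '", network$reactions[[j]]$name,
           "' is ", a[j], " at t=", t, " state=",
           paste(x, collapse = ","))
    }
    # mask reactions that would drive a species negative
    for (j in which(a > 0)) {
      if (any(x + D[j, ] < 0)) a[j] <- 0
    }
    a0 <- sum(a)
    if (a0 <= 0) { absorbed <- TRUE; break }
    r1 <- runif(1)
    t_new <- t + log(1 / r1) / a0
    if (t_new > t_max) { t <- t_max; break }
    while (gi <= G && grid[gi] < t_new) { grid_states[gi, ] <- x; gi <- gi + 1L }
    r2 <- runif(1)
    j_sel <- which(cumsum(a) / a0 > r2)[1]
    if (is.na(j_sel)) j_sel <- length(a)
    x <- x + D[j_sel, ]
    t <- t_new
    n_events <- n_events + 1
    if (recording == "every_event") {
      ev_t[[length(ev_t) + 1L]] <- t; ev_x[[length(ev_x) + 1L]] <- x
    }
    if (n_events >= max_events) stop("event budget exceeded at t=", t)
  }
  if (recording == "every_event") {
    states <- do.call(rbind, ev_x)
    times <- unlist(ev_t)
  } else {
    while (gi <= G) { grid_states[gi, ] <- x; gi <- gi + 1L }
    states <- grid_states
    times <- grid
  }
  meta <- c(network$meta["params"],
            list(seed = seed, t_max = t_max, n_events = n_events, engine = "r"))
  new_trajectory(times, states, network, meta, absorbed = absorbed)
}

#' Deterministic (mass-action mean-field) twin of a reaction network
#'
#' Integrates `dx/dt = t(S) %*% a(x)` where `a` are the same propensity
#' functions used by the stochastic engine evaluated at continuous state,
#' and `S` is the stoichiometry matrix. Uses a stiff-capable adaptive
#' integrator (`deSolve::lsoda`).
#'
#' @param network A [reaction_network()] (or a plain rhs `function(t, y)`
#'   together with `y0`).
#' @param t_max End time (s).
#' @param rtol,atol Integration tolerances.
#' @param n_grid Number of output grid intervals.
#' @param y0 Initial state override (named numeric), defaults to the
#'   network's initial counts.
#' @return A `trajectory` with continuous states.
#' @export
simulate_ode <- function(network, t_max, rtol = 1e-8, atol = 1e-8,
                         n_grid = 500L, y0 = NULL) {
  stopifnot(t_max > 0)
  grid <- seq(0, t_max, length.out = n_grid + 1L)
  if (inherits(network, "reaction_network")) {
    D <- delta_matrix(network)
    y0 <- if (is.null(y0)) network$initial_state else y0[network$species]
    rhs <- function(t, y, parms) {
      a <- eval_propensities(network, setNames(pmax(y, 0), network$species), t)
      list(as.numeric(crossprod(D, a)))
    }
    sol <- deSolve::ode(y = y0, times = grid, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed at t=", max(sol[, "time"]))
    states <- sol[, network$species, drop = FALSE]
    colnames(states) <- network$species
    return(new_trajectory(sol[, "time"], states, network,
                          meta = c(network$meta["params"],
                                   list(engine = "ode", rtol = rtol))))
  }
  stop("`network` must be a reaction_network")
}

#' Run a seeded ensemble of stochastic simulations
#'
#' Runs `n_runs` independent simulations with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n_runs - 1` and applies one or
#' more reducer functions to each trajectory. Fully reproducible: the same
#' factory and base seed yield the same summary.
#'
#' @param network_factory Either a [reaction_network()] (used for every run)
#'   or a function `seed -> reaction_network` (e.g. to jitter initial
#'   conditions per run).
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First seed.
#' @param t_max End time per run (s).
#' @param reducers Named list of functions `trajectory -> scalar`.
#' @param ... Passed to [simulate_ssa()].
#' @return An `ensemble_summary`: data frame with one row per run (columns
#'   `seed`, then one per reducer) plus attributes `base_seed`, `t_max`.
#' @export
run_ensemble <- function(network_factory, n_runs, base_seed = 1L, t_max,
                         reducers = list(final = function(tr)
                           tail(tr$states, 1L)), ...) {
  stopifnot(n_runs >= 1)
  seeds <- base_seed + seq_len(n_runs) - 1L
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    network <- if (is.function(network_factory)) network_factory(seeds[i])
               else network_factory
    tr <- tryCatch(simulate_ssa(network, t_max = t_max, seed = seeds[i], ...),
                   error = function(e) stop("run ", i, " (seed ", seeds[i],
                                            ") failed: ", conditionMessage(e)))
    vals <- unlist(lapply(reducers, function(f) f(tr)))
    rows[[i]] <- c(seed = seeds[i], vals)
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "base_seed") <- base_seed
  attr(out, "t_max") <- t_max
  class(out) <- c("ensemble_summary", class(out))
  out
}

#' Write a trajectory to tidy CSV with a JSON metadata sidecar
#'
#' @param trajectory A `trajectory`.
#' @param csv_path Output CSV path (`time`, species..., derived... columns).
#' @param json_path Optional path for a JSON sidecar holding the run
#'   metadata (seed, parameters, unit convention, package version).
#' @return `csv_path`, invisibly.
#' @export
write_trajectory <- function(trajectory, csv_path, json_path = NULL) {
  write.csv(as.data.frame(trajectory), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- trajectory$meta
    meta$package_version <- as.character(utils::packageVersion("centrosim"))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(csv_path)
}
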