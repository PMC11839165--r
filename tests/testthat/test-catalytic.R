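test_that("catalytic growth law: no growth without enzyme or centriolar route", {
  p <- catalytic_params(k_plus = 0, k_star = 1000, k1_star = 1, kE_star = 5,
                        rho0 = 1, E_conc = 0.1)
  d <- catalytic_rhs(c(100, 80, 0, 0), p)
  expect_equal(d[1:2], -p$k_minus * c(100, 80))
  # symmetric states stay symmetric
  p2 <- catalytic_params(k_plus = 1, k_star = 1000, k1_star = 1, kE_star = 5,
                         rho0 = 1, E_conc = 0.1)
  d2 <- catalytic_rhs(c(50, 50, 10, 20), p2)
  expect_equal(d2[1], d2[2])
  expect_error(catalytic_rhs(c(p2$N, 10, 5, 0), p2), "constraint")
})

test_that("network mean field matches the dedicated pair growth law", {
  p <- catalytic_params(k_plus = 1, k_star = 1000, k1_star = 1, kE_star = 5,
                        rho0 = 1, E_conc = 0.1)
  net <- build_catalytic_network(p, c(40L, 20L))
  df <- as.data.frame(simulate_ode(net, t_max = 800, n_grid = 100))
  # integrate the rhs directly and compare at the end point
  y <- c(40, 20, 0, 0)
  sol <- deSolve::ode(y = y, times = seq(0, 800, 4),
                      func = function(t, y, p) list(catalytic_rhs(y, p)),
                      parms = p, rtol = 1e-8, atol = 1e-8)
  expect_equal(tail(df$Sn1, 1), unname(tail(sol[, 2], 1)), tolerance = 1e-4)
  expect_equal(tail(df$Es, 1), unname(tail(sol[, 5], 1)), tolerance = 1e-3)
})

test_that("SSA ensemble mean tracks the ODE for the catalytic pair", {
  sc <- load_scenario("fig3c", units = "unity")
  net <- scenario_network(sc)
  idx <- c(26L, 51L)  # t = 1000, 2000 on a 50-interval grid
  acc <- matrix(0, 2, 2)
  n_runs <- 300
  for (s in seq_len(n_runs)) {
    tr <- simulate_ssa(net, t_max = 2000, seed = s, n_grid = 50)
    acc <- acc + tr$states[idx, c("Sn1", "Sn2")]
  }
  ode <- simulate_ode(net, t_max = 2000, n_grid = 50)
  rel <- abs(acc / n_runs - ode$states[idx, c("Sn1", "Sn2")]) /
    ode$states[idx, c("Sn1", "Sn2")]
  expect_lt(max(rel), 0.05)
})

test_that("both conserved totals hold exactly along SSA paths", {
  sc <- load_scenario("fig3c", units = "unity")
  net <- scenario_network(sc)
  tr <- simulate_ssa(net, t_max = 300, seed = 11, recording = "every_event")
  expect_true(all(tr$states[, "Sn1"] + tr$states[, "Sn2"] +
                    tr$states[, "S1"] + tr$states[, "S1s"] == sc$params$N))
  expect_true(all(tr$states[, "E"] + tr$states[, "Es"] +
                    tr$states[, "S1s"] == sc$params$NE))
})

test_that("closed-form steady state obeys its algebraic limits", {
  p <- catalytic_params(k_plus = 2, k_star = 500, k1_star = 3, kE_star = 5,
                        k_minus = 0, rho0 = 0.5, E_conc = 0.1)
  cVc <- p$units$count_per_uM_um3 * p$Vc
  expect_equal(steady_state_volume(p, E_star_ss = 1000),
               0.5 * cVc * p$delta_v)  # complete conversion when k- = 0
  p2 <- catalytic_params(k_plus = 2, k_star = 500, k1_star = 3, kE_star = 5,
                         rho0 = 0.5, E_conc = 0.1)
  km_eff <- p2$k_minus * cVc
  expect_equal(steady_state_volume(p2, E_star_ss = 0),
               2 * 0.5 * cVc * p2$delta_v / (2 + km_eff))
})

test_that("closed form with self-consistent E* matches long-time integration", {
  # a small random parameter sample around the published magnitudes
  set.seed(4)
  for (i in 1:3) {
    p <- catalytic_params(k_plus = runif(1, 0.5, 2),
                          k_star = runif(1, 500, 2000),
                          k1_star = runif(1, 0.5, 5),
                          kE_star = runif(1, 2, 10),
                          rho0 = runif(1, 0.05, 0.5),
                          E_conc = runif(1, 0.05, 0.2))
    net <- build_catalytic_network(p, 25L)
    df <- as.data.frame(simulate_ode(net, t_max = 4e4))
    expect_equal(tail(df$V1, 1), steady_state_volume(p), tolerance = 0.01)
  }
})

test_that("unlimited enzyme mode keeps growing enzyme and depletes inactive subunits", {
  sc <- load_scenario("fig3gh")
  expect_identical(sc$params$enzyme_mode, "unlimited_pool")
  net <- scenario_network(sc)
  df <- as.data.frame(simulate_ode(net, t_max = 20000, n_grid = 200))
  last <- df[nrow(df), ]
  # steady state exists and the free inactive pool is far below the active
  expect_lt(last$S1, 0.1 * last$S1s)
  expect_equal(last$V1, last$V2, tolerance = 1e-6)
})

test_that("pulse metrics behave on constructed and model series", {
  # triangular pulse of height h and base w has FWHM w/2
  tt <- seq(0, 10, 0.01)
  y <- pmax(0, 4 - abs(tt - 5) * (2 * 4 / 4))  # h = 4, base w = 4
  tr <- structure(list(times = tt,
                       states = matrix(y, ncol = 1,
                                       dimnames = list(NULL, "Es"))),
                  class = "trajectory")
  pm <- pulse_metrics(tr, "Es")
  expect_true(pm$pulse)
  expect_equal(pm$amplitude, 4)
  expect_equal(pm$peak_time, 5)
  expect_equal(pm$lifetime, 2, tolerance = 0.02)
  # no enzyme activation, no pulse
  p0 <- catalytic_params(k_plus = 1, k_star = 1000, k1_star = 1, kE_star = 0,
                         rho0 = 1, E_conc = 0.1)
  tr0 <- simulate_ode(build_catalytic_network(p0, c(25L, 25L)), t_max = 1000)
  pm0 <- pulse_metrics(tr0, "Es")
  expect_false(pm0$pulse)
  expect_equal(pm0$amplitude, 0)
})

test_that("halving the enzyme activation rate lowers and widens the pulse", {
  sc <- load_scenario("fig3c")
  tr1 <- simulate_ode(scenario_network(sc), t_max = 3000)
  sc2 <- load_scenario("fig3c",
                       overrides = list(params = list(kE_star = 2.5)))
  tr2 <- simulate_ode(scenario_network(sc2), t_max = 3000)
  pm1 <- pulse_metrics(tr1, "Es")
  pm2 <- pulse_metrics(tr2, "Es")
  expect_true(pm1$pulse && pm2$pulse)
  expect_lt(pm2$amplitude, pm1$amplitude)
  expect_gt(pm2$lifetime, pm1$lifetime)
})

test_that("growth is sigmoidal for high enzyme/low centriolar activity and not otherwise", {
  base <- list(k_star = 1000, k1_star = 10, kE_star = 5, rho0 = 1)
  alpha_of <- function(kp, E) {
    p <- do.call(catalytic_params, c(base, list(k_plus = kp, E_conc = E)))
    df <- as.data.frame(simulate_ode(build_catalytic_network(p, 25L),
                                     t_max = 20000, n_grid = 300))
    fit_hill(df$time, df$V1)$alpha
  }
  expect_gte(alpha_of(0.1, 0.5), 2)   # high [E], low k+
  expect_lt(alpha_of(100, 0.01), 2)   # low [E], high k+
})
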