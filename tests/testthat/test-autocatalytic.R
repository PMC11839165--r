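fx <- fixed_params()

test_that("growth law has the documented fixed points and depletion limit", {
  p <- autocatalytic_params(k0_plus = 0, k1_plus = 0.6, rho0 = 0.033)
  expect_equal(autocatalytic_rhs(c(0, 0), p), c(0, 0))
  # depleted pool can only shrink
  p2 <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, N = 100)
  d <- autocatalytic_rhs(c(60, 40), p2)
  expect_equal(d, -p2$k_minus * c(60, 40))
  expect_error(autocatalytic_rhs(c(80, 40), p2), "simplex")
})

test_that("symmetric steady state from root-finding matches long-time ODE", {
  p <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033)
  cVc <- p$units$count_per_uM_um3 * p$Vc
  f <- function(n) (p$k0_plus + p$k1_plus * n) * (p$N - 2 * n) / cVc -
    p$k_minus * n
  n_star <- uniroot(f, c(1, p$N / 2), tol = 1e-10)$root
  net <- build_autocatalytic_network(p, c(25L, 25L))
  df <- as.data.frame(simulate_ode(net, t_max = 3e4, rtol = 1e-10,
                                   atol = 1e-10))
  expect_equal(tail(df$n1, 1), n_star, tolerance = 1e-6)
})

test_that("SSA mean of the pair model tracks the ODE mean field", {
  # reduced-count scale keeps the ensemble cheap; the mean-field limit is
  # scale-free
  p <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033,
                            units = "unity")
  net <- build_autocatalytic_network(p, c(25L, 25L))
  grid_idx <- c(11L, 26L, 51L)   # t = 400, 1000, 2000 on a 50-point grid
  acc <- matrix(0, length(grid_idx), 2)
  n_runs <- 400
  for (s in seq_len(n_runs)) {
    tr <- simulate_ssa(net, t_max = 2000, seed = s, n_grid = 50)
    acc <- acc + tr$states[grid_idx, c("n1", "n2")]
  }
  ssa_mean <- acc / n_runs
  ode <- simulate_ode(net, t_max = 2000, n_grid = 50)
  ode_vals <- ode$states[grid_idx, c("n1", "n2")]
  expect_lt(max(abs(ssa_mean - ode_vals) / ode_vals), 0.05)
})

test_that("subunit conservation is exact along SSA paths", {
  p <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033,
                            units = "unity")
  net <- build_autocatalytic_network(p, c(20L, 30L))
  tr <- simulate_ssa(net, t_max = 500, seed = 3, recording = "every_event")
  expect_true(all(rowSums(tr$states) == p$N))
})

test_that("non-cooperative growth equalizes a pair started unequal", {
  p <- autocatalytic_params(k0_plus = 1000, k1_plus = 0, rho0 = 0.1,
                            units = "unity")
  net <- build_autocatalytic_network(p, c(20L, 30L))
  finals <- vapply(1:150, function(s) {
    st <- pair_at(simulate_ssa(net, t_max = 2500, seed = s, n_grid = 20), 2500)
    st$V1 - st$V2
  }, numeric(1))
  meanV <- p$N * p$delta_v / 2 / 2   # rough per-centrosome scale
  expect_lt(abs(mean(finals)) / meanV, 0.05)
})

test_that("non-cooperative closed-form volume matches algebra and ODE", {
  u <- unit_system()
  expect_equal(noncooperative_steady_volume(5, N = 1000, k_minus = 0,
                                            delta_v = 2e-4, units = u),
               1000 * 2e-4 / 2)
  # k- matched to 2 k+ on the bimolecular scale gives N delta_v / 4
  cVc <- u$count_per_uM_um3 * 5000
  kp <- 7
  expect_equal(noncooperative_steady_volume(kp, N = 1000,
                                            k_minus = 2 * kp / cVc,
                                            delta_v = 2e-4, units = u),
               1000 * 2e-4 / 4)
  # Fig-2D-style scenario: closed form vs long-time ODE within 1%
  p <- autocatalytic_params(k0_plus = 1000, k1_plus = 0, rho0 = 0.1)
  net <- build_autocatalytic_network(p, c(25L, 25L))
  df <- as.data.frame(simulate_ode(net, t_max = 2e4))
  Vform <- noncooperative_steady_volume(1000, p$N, p$k_minus, p$Vc,
                                        p$delta_v, p$units)
  expect_equal(tail(df$V1, 1), Vform, tolerance = 0.01)
})

test_that("the size-equality condition evaluates the printed inequality", {
  expect_true(equality_condition_holds(
    autocatalytic_params(k0_plus = 5, k1_plus = 0, rho0 = 1)))
  p_auto <- autocatalytic_params(k0_plus = 0, k1_plus = 1, k_minus = 0,
                                 N = 10)
  expect_false(equality_condition_holds(p_auto))
  # the published autocatalytic scenario predicts size inequality
  expect_false(equality_condition_holds(
    autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033)))
})

test_that("exchange symmetry: swapping labels swaps deterministic outcomes", {
  p <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033)
  a <- as.data.frame(simulate_ode(build_autocatalytic_network(p, c(20L, 30L)),
                                  t_max = 1000, n_grid = 50))
  b <- as.data.frame(simulate_ode(build_autocatalytic_network(p, c(30L, 20L)),
                                  t_max = 1000, n_grid = 50))
  expect_equal(a$n1, b$n2, tolerance = 1e-8)
  expect_equal(a$n2, b$n1, tolerance = 1e-8)
})

test_that("purely autocatalytic final |dV| is monotone in the initial difference", {
  p <- autocatalytic_params(k0_plus = 0.06, k1_plus = 0.6, rho0 = 0.033,
                            units = "unity")
  mean_abs <- vapply(c(2L, 6L, 12L, 20L), function(dn) {
    finals <- vapply(1:60, function(s) {
      net <- build_autocatalytic_network(p, c(25L + dn, 25L - dn))
      st <- pair_at(simulate_ssa(net, t_max = 2000, seed = s, n_grid = 20),
                    2000)
      abs(st$V1 - st$V2)
    }, numeric(1))
    mean(finals)
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("the literal size-independent disassembly variant is available", {
  p <- autocatalytic_params(k0_plus = 600, k1_plus = 0.6, rho0 = 0.033,
                            units = "unity", off_literal = TRUE)
  net <- build_autocatalytic_network(p, c(25L, 25L))
  tr <- simulate_ssa(net, t_max = 200, seed = 1)
  expect_true(all(tr$states >= 0))
})
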