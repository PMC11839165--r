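test_that("network construction validates species, counts and conserved sums", {
  expect_error(reaction_network("A", c(B = 1), list()), "match species")
  expect_error(reaction_network("A", c(A = -1), list()), "non-negative")
  expect_error(
    reaction_network("A", c(A = 1),
                     list(reaction("r", c(Z = 1), rate_spec(1, affine("A"))))),
    "unknown species")
  expect_error(
    reaction_network(c("A", "B"), c(A = 3, B = 0),
                     list(reaction("r", c(A = -1, B = 1),
                                   rate_spec(1, affine("A")))),
                     conserved = list(list(coef = c(A = 1, B = 1), total = 5))),
    "conserved")
})

test_that("pure-death SSA ensemble matches the analytic mean", {
  net <- pure_death_network(100L, 0.01)
  finals <- vapply(1:1000, function(s) {
    tail(simulate_ssa(net, t_max = 100, seed = s, n_grid = 10)$states[, "n"], 1)
  }, numeric(1))
  mu <- 100 * exp(-1)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - mu), 3 * se + 1e-9)
})

test_that("birth-death SSA reaches the Poisson stationary mean", {
  net <- birth_death_network(0L, b = 5, d = 0.1)
  tr <- simulate_ssa(net, t_max = 3000, seed = 7, n_grid = 1500)
  n <- tr$states[tr$times > 200, "n"]  # discard burn-in
  # decorrelation time is 1/d = 10 s; grid spacing is 2 s
  n_eff <- length(n) / (10 / 2)
  se <- sqrt(50 / n_eff)
  expect_lt(abs(mean(n) - 50), 3 * se)
})

test_that("reversible isomerization matches the binomial equilibrium law", {
  net <- isomerization_network(50L, 1, 1)
  tr <- simulate_ssa(net, t_max = 2000, seed = 3, n_grid = 1000)
  A <- tr$states[tr$times > 20, "A"]
  n_eff <- length(A) / ((1 / 2) / 2)   # tau_corr = 1/(k12+k21)
  se <- sqrt(50 * 0.25 / max(n_eff, 1))
  expect_lt(abs(mean(A) - 25), 3 * se)
  check_conserved(net, tr)
})

test_that("all-zero propensities give an absorbed single-record trajectory", {
  net <- reaction_network("n", c(n = 0),
                          list(reaction("death", c(n = -1),
                                        rate_spec(1, affine("n")))))
  tr <- simulate_ssa(net, t_max = 10, seed = 1, recording = "every_event")
  expect_true(tr$absorbed)
  expect_identical(nrow(tr$states), 1L)
})

test_that("same seed gives a bit-identical event sequence", {
  net <- birth_death_network(0L, 5, 0.1)
  a <- simulate_ssa(net, t_max = 50, seed = 42, recording = "every_event")
  b <- simulate_ssa(net, t_max = 50, seed = 42, recording = "every_event")
  expect_identical(a$times, b$times)
  expect_identical(a$states, b$states)
  c <- simulate_ssa(net, t_max = 50, seed = 43, recording = "every_event")
  expect_false(identical(a$times, c$times))
})

test_that("compiled and reference engines draw identical trajectories", {
  net <- isomerization_network(30L, 0.5, 0.8)
  a <- simulate_ssa(net, t_max = 30, seed = 5, recording = "every_event")
  b <- simulate_ssa(net, t_max = 30, seed = 5, recording = "every_event",
                    engine = "r")
  expect_equal(a$times, b$times)
  expect_equal(unname(a$states), unname(b$states))
})

test_that("R-function propensities run on the reference engine", {
  finals <- vapply(1:200, function(s) {
    tail(simulate_ssa(pure_death_network_r(50L, 0.02), t_max = 50,
                      seed = s, n_grid = 5)$states[, "n"], 1)
  }, numeric(1))
  mu <- 50 * exp(-1)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - mu), 3 * se)
})

test_that("negative or NaN propensities abort with a diagnostic", {
  net <- reaction_network("n", c(n = 5),
                          list(reaction("bad", c(n = -1),
                                        propensity = function(state, t) NaN)))
  expect_error(simulate_ssa(net, t_max = 10, seed = 1), "bad")
})

test_that("the ODE twin reproduces closed forms and conserved sums", {
  net <- pure_death_network(100L, 0.01)
  tr <- simulate_ode(net, t_max = 100, n_grid = 50)
  expect_equal(tr$states[, "n"], 100 * exp(-0.01 * tr$times),
               tolerance = 1e-6)
  # zero-rate network stays constant
  net0 <- reaction_network("n", c(n = 7),
                           list(reaction("nil", c(n = -1),
                                         rate_spec(0, affine("n")))))
  tr0 <- simulate_ode(net0, t_max = 10, n_grid = 10)
  expect_true(all(tr0$states[, "n"] == 7))
  # conservation to integration tolerance
  iso <- isomerization_network(50L, 1, 2)
  tri <- simulate_ode(iso, t_max = 10)
  expect_lt(max(abs(rowSums(tri$states) - 50)), 1e-6)
})

test_that("run_ensemble is reproducible and reduces per run", {
  net <- birth_death_network(0L, 5, 0.1)
  red <- list(final_n = function(tr) tail(tr$states[, "n"], 1))
  a <- run_ensemble(net, n_runs = 10, base_seed = 9, t_max = 20,
                    reducers = red, n_grid = 10)
  b <- run_ensemble(net, n_runs = 10, base_seed = 9, t_max = 20,
                    reducers = red, n_grid = 10)
  expect_identical(a$final_n, b$final_n)
  expect_identical(a$seed, 9 + 0:9)
  one <- run_ensemble(net, n_runs = 1, base_seed = 4, t_max = 20,
                      reducers = red, n_grid = 10)
  solo <- simulate_ssa(net, t_max = 20, seed = 4, n_grid = 10)
  expect_identical(one$final_n[1], unname(tail(solo$states[, "n"], 1)))
})

test_that("trajectory CSV/JSON writers round-trip the data", {
  net <- isomerization_network(20L)
  tr <- simulate_ssa(net, t_max = 5, seed = 2, n_grid = 20)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_trajectory(tr, csv, js)
  back <- read.csv(csv)
  expect_equal(back$A, unname(tr$states[, "A"]))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$seed, 2)
})
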