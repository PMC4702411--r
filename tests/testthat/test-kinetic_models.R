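test_that("compartment solution satisfies the known analytic limits", {
  # no transfer, no production: mono-exponential elimination
  p <- compartment_params(1000, 0, 0, 0.1, 0, "none")
  expect_equal(solve_compartment_numeric(p, 10), 1000 * exp(-1),
               tolerance = 1e-5)
  expect_equal(solve_compartment_closed_form(p, 10), 1000 * exp(-1),
               tolerance = 1e-12)
  # initial condition holds exactly
  p2 <- compartment_params(5000, 0.8, 0.3, 0.5, 100, "constant")
  expect_identical(solve_compartment_closed_form(p2, 0), 5000)
  expect_equal(solve_compartment_numeric(p2, 0), 5000)
  # constant production: mu1 tends to the steady state A / k10
  expect_equal(solve_compartment_closed_form(p2, 500), 100 / 0.5,
               tolerance = 1e-9)
})

test_that("closed-form and LSODA solutions agree", {
  p <- compartment_params(5000, 0.8, 0.3, 0.5, 0, "none")
  t <- c(1, 3, 7, 14, 21)
  cf <- solve_compartment_closed_form(p, t)
  nm <- solve_compartment_numeric(p, t)
  expect_equal(nm, cf, tolerance = 1e-6)
})

test_that("closed-form matches LSODA over random kinetic draws", {
  set.seed(7)
  t <- seq(0, 21, by = 1.5)
  worst <- 0
  for (i in 1:100) {
    kind <- sample(c("none", "constant", "linear"), 1)
    p <- compartment_params(
      mu10 = 10^stats::runif(1, 2, 6),
      k12 = exp(stats::runif(1, log(0.01), log(2))),
      k21 = exp(stats::runif(1, log(0.01), log(2))),
      k10 = exp(stats::runif(1, log(0.01), log(2))),
      A = if (kind == "none") 0 else stats::runif(1, 0, 500),
      production = kind)
    cf <- solve_compartment_closed_form(p, t)
    nm <- solve_compartment_numeric(p, t)
    worst <- max(worst, max(abs(nm - cf) / pmax(abs(cf), 1e-8)))
  }
  expect_lt(worst, 1e-5)
})

test_that("mass is conserved without elimination or production", {
  # independent oracle: integrate both compartments with deSolve directly
  p <- compartment_params(2000, 0.9, 0.4, 0, 0, "none")
  rhs <- function(t, y, parms)
    list(c(-(0.9 + 0) * y[1] + 0.4 * y[2], 0.9 * y[1] - 0.4 * y[2]))
  out <- deSolve::lsoda(c(2000, 0), seq(0, 21, 0.5), rhs, NULL,
                        atol = 1e-10, rtol = 1e-10)
  expect_equal(out[, 2] + out[, 3], rep(2000, nrow(out)), tolerance = 1e-7)
  expect_equal(solve_compartment_closed_form(p, out[, 1]),
               unname(out[, 2]), tolerance = 1e-6)
})

test_that("the homogeneous compartment solution is bi-exponential", {
  # oracle: eigen-decompose the transfer matrix with base::eigen and build
  # the equivalent c exp(a t) + c2 exp(a2 t) representation
  k12 <- 0.8; k21 <- 0.3; k10 <- 0.5; mu10 <- 5000
  M <- matrix(c(-(k12 + k10), k21, k12, -k21), 2, 2, byrow = TRUE)
  e <- eigen(M)
  alpha <- solve(e$vectors, c(mu10, 0))
  bp <- biexp_params(c = alpha[1] * e$vectors[1, 1], a = e$values[1],
                     c2 = alpha[2] * e$vectors[1, 2], a2 = e$values[2])
  t <- seq(0, 21, by = 0.5)
  p <- compartment_params(mu10, k12, k21, k10, 0, "none")
  expect_equal(biexp_predict(bp, t), solve_compartment_closed_form(p, t),
               tolerance = 1e-10)
})

test_that("biexp_predict evaluates pointwise", {
  expect_equal(biexp_predict(biexp_params(1000, -0.5, 0, 0), 2),
               1000 * exp(-1))
  expect_equal(biexp_predict(biexp_params(300, -0.2, 450, -0.01), 0), 750)
})

test_that("mean_log_trajectory is the log of the concentration path", {
  p <- compartment_params(1000, 0.7, 0.25, 0.6, 50, "constant")
  expect_equal(mean_log_trajectory(p, 0), log(1000))
  t <- c(0.5, 2, 9, 18)
  expect_equal(mean_log_trajectory(p, t),
               log(solve_compartment_numeric(p, t)), tolerance = 1e-7)
  # negative concentrations are flagged, not silently logged
  expect_error(mean_log_trajectory(biexp_params(500, 0, -600, 0), c(1, 2)),
               "invalid mean trajectory")
})
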