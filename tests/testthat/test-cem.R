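test_that("C-step takes the row argmax with low-index tie-breaking", {
  expect_identical(c_step(matrix(c(0.2, 0.5, 0.3), 1)), 2L)
  expect_identical(c_step(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(2)
  m <- matrix(stats::runif(300), 100, 3)
  m <- m / rowSums(m)
  expect_identical(c_step(m),
                   vapply(seq_len(nrow(m)), function(i) which.max(m[i, ]), 1L))
})

test_that("stochastic C-step draws one multinomial trial per subject", {
  expect_identical(stochastic_c_step(matrix(c(1, 0), 1)), 1L)
  set.seed(9)
  draws <- stochastic_c_step(matrix(0.5, 1e4, 2))
  freq <- mean(draws == 1)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 1e4))
  # seeded determinism
  m <- matrix(c(0.3, 0.7), 50, 2, byrow = TRUE)
  set.seed(4); a <- stochastic_c_step(m)
  set.seed(4); b <- stochastic_c_step(m)
  expect_identical(a, b)
})

test_that("M-step recovers generating parameters from near-noiseless data", {
  true <- compartment_params(5000, 0.8, 0.3, 0.5, 0, "none")
  times <- seq(0.5, 21, length.out = 12)
  set.seed(8)
  subj <- rep(sprintf("s%02d", 1:8), each = 12)
  mu <- rep(log(solve_compartment_closed_form(true, times)), 8)
  y <- mu + stats::rnorm(length(mu), 0, 1e-4)
  coh <- cohort_from_long(subj, rep(times, 8), exp(y))
  spec <- model_spec("compartment", "none", 1, "shared")
  st <- m_step(coh, rep(1L, 8), spec, fit_config())
  expect_equal(unname(st$kinetics), c(0.8, 0.3, 0.5), tolerance = 1e-2)
  expect_equal(st$groups[[1]]$mu10, 5000, tolerance = 1e-3)
  expect_lt(st$sigma2, 1e-6)
  expect_equal(st$pi, 1)
})

test_that("M-step estimates mixing weights as group frequencies and rejects
           degenerate cases", {
  sc <- separated_scenario(30)
  coh <- simulate_cohort(sc, seed = 31)
  truth <- attr(coh, "truth")$group
  st <- m_step(coh, truth, sc$spec, fit_config())
  expect_equal(st$pi, tabulate(truth, 2) / 30)
  expect_error(m_step(coh, rep(1L, 30), sc$spec, fit_config()),
               "empty group")
  # exactly zero residuals leave no admissible variance estimate
  p <- compartment_params(1000, 0.7, 0.25, 0.6, 0, "none")
  tt <- c(1, 5, 9, 14)
  exact <- cohort_from_long(rep(c("a", "b"), each = 4), rep(tt, 2),
                            rep(solve_compartment_closed_form(p, tt), 2))
  expect_error(m_step(exact, rep(1L, 2),
                      model_spec("compartment", "none", 1, "shared"),
                      fit_config()),
               "degenerate variance")
})

test_that("SEM initialization separates well-separated groups and is
           reproducible", {
  sc <- separated_scenario(50)
  coh <- simulate_cohort(sc, seed = 13)
  truth <- attr(coh, "truth")$group
  cfg <- fast_config(seed = 13)
  set.seed(13)
  sem <- sem_initialize(coh, sc$spec, cfg, .set_seed = FALSE)
  # agreement with the generating groups (labels already level-aligned)
  expect_gte(mean(sem$assignment == truth), 0.95)
  # same seed twice: identical output
  a <- sem_initialize(coh, sc$spec, cfg)
  b <- sem_initialize(coh, sc$spec, cfg)
  expect_identical(a, b)
  # zero SEM iterations: the M-step fit of the initial random partition
  cfg0 <- fast_config(seed = 5, sem_iterations = 0)
  z0 <- withr::with_seed(5, sample(rep_len(1:2, 50)))
  boot <- sem_initialize(coh, sc$spec, cfg0)
  st0 <- m_step(coh, z0, sc$spec, cfg0)
  rl0 <- kinclust:::.relabel(st0, z0, sc$spec)
  expect_equal(boot$structure, rl0$structure)
  expect_identical(boot$assignment, rl0$assignment)
})

test_that("CEM recovers well-separated groups with a non-decreasing
           classification log-likelihood", {
  sc <- separated_scenario(60)
  coh <- simulate_cohort(sc, seed = 17)
  truth <- attr(coh, "truth")$group
  fit <- cem_fit(coh, sc$spec, fast_config(seed = 17))
  expect_true(fit$converged)
  expect_lt(100 * mean(unname(fit$assignment) != truth), 5)
  # monotone trace after the first complete iteration
  d <- diff(fit$lc_trace)
  expect_true(all(d >= -1e-9 * abs(fit$lc_trace[-length(fit$lc_trace)])))
  expect_equal(sum(fit$group_sizes), 60L)
})

test_that("CEM is deterministic given a seed", {
  sc <- separated_scenario(40)
  coh <- simulate_cohort(sc, seed = 23)
  f1 <- cem_fit(coh, sc$spec, fast_config(seed = 99))
  f2 <- cem_fit(coh, sc$spec, fast_config(seed = 99))
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$criteria, f2$criteria)
  expect_identical(f1$lc_trace, f2$lc_trace)
})

test_that("a one-group fit reduces to a plain least-squares fit", {
  sc <- separated_scenario(20)
  sc$mu10 <- sc$mu10[1]; sc$A <- 0; sc$pi <- 1; sc$G <- 1L
  sc$spec <- model_spec("compartment", "constant", 1, "shared")
  sc$diseased_groups <- integer(0)
  coh <- simulate_cohort(sc, seed = 3)
  fit <- cem_fit(coh, sc$spec, fast_config(seed = 3))
  # with one component the classification and mixture likelihoods coincide
  expect_equal(fit$lc, fit$loglik, tolerance = 1e-9)
})

test_that("perturbing a deeply separated fit does not move subjects", {
  sc <- separated_scenario(40)
  coh <- simulate_cohort(sc, seed = 29)
  cfg <- fast_config(seed = 29)
  fit <- cem_fit(coh, sc$spec, cfg)
  # null perturbation: identical refit
  r0 <- perturb_and_refit(coh, sc$spec, cfg, fit, n_moved_per_group = 0,
                          seed = 1)
  expect_identical(r0$n_changed, 0L)
  expect_equal(r0$lc_delta, 0, tolerance = 1e-8)
  # real perturbation: strong basin of attraction pulls everyone back
  r <- perturb_and_refit(coh, sc$spec, cfg, fit, n_moved_per_group = 5,
                         seed = 2)
  expect_identical(r$n_changed, 0L)
})

test_that("the bi-exponential model fits grouped trajectories", {
  sc <- separated_scenario(40)
  coh <- simulate_cohort(sc, seed = 37)
  truth <- attr(coh, "truth")$group
  spec <- model_spec("biexp", n_groups = 2, variance = "shared")
  fit <- cem_fit(coh, spec, fast_config(seed = 37))
  expect_true(fit$converged)
  expect_lt(100 * mean(unname(fit$assignment) != truth), 5)
})
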