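# small two-group structure used across likelihood tests
toy_structure <- function(sigma2 = 1, pi = c(0.5, 0.5),
                          variance = "shared") {
  spec <- model_spec("compartment", "constant", 2, variance)
  list(spec = spec,
       st = group_structure(
         spec,
         groups = list(list(mu10 = 1e3, A = 0), list(mu10 = 1e5, A = 500)),
         pi = pi,
         sigma2 = if (variance == "per_group") rep(sigma2, 2) else sigma2,
         kinetics = c(k12 = 0.7, k21 = 0.25, k10 = 0.6)))
}

test_that("group log-density matches the diagonal Gaussian formula", {
  toy <- toy_structure()
  p1 <- kinclust:::.group_params(toy$st, 1, toy$spec)
  t <- c(1, 6)
  mu <- log(solve_compartment_closed_form(p1, t))
  # one measurement exactly on the mean, unit variance
  tr1 <- list(time = t[1], log_hcg = mu[1])
  expect_equal(log_density_group(tr1, 1, toy$st, toy$spec),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # additivity over measurements
  tr2 <- list(time = t, log_hcg = mu)
  expect_equal(log_density_group(tr2, 1, toy$st, toy$spec),
               -log(2 * pi), tolerance = 1e-12)
  # random trajectory vs the textbook normal log-pdf
  set.seed(3)
  y <- mu + stats::rnorm(2)
  expect_equal(log_density_group(list(time = t, log_hcg = y), 1, toy$st, toy$spec),
               sum(stats::dnorm(y, mean = mu, sd = 1, log = TRUE)),
               tolerance = 1e-12)
})

test_that("classification log-likelihood is the brute-force sum", {
  toy <- toy_structure(sigma2 = 0.5, pi = c(0.7, 0.3))
  sc <- separated_scenario(3)
  coh <- simulate_cohort(sc, seed = 11)
  z <- c(1L, 2L, 1L)
  brute <- 0
  for (i in 1:3) {
    tr <- get_trajectory(coh, i)
    brute <- brute + log(toy$st$pi[z[i]]) +
      log_density_group(tr, z[i], toy$st, toy$spec)
  }
  expect_equal(classification_loglik(coh, z, toy$st, toy$spec), brute,
               tolerance = 1e-12)
})

test_that("classification log-likelihood is additive over subjects", {
  toy <- toy_structure()
  sc <- separated_scenario(4)
  coh <- simulate_cohort(sc, seed = 5)
  z <- c(1L, 2L, 1L, 2L)
  lc1 <- classification_loglik(coh, z, toy$st, toy$spec)
  dup <- cohort_from_long(
    c(coh$data$subject_id, paste0(coh$data$subject_id, "_copy")),
    rep(coh$data$time, 2), rep(coh$data$hcg, 2))
  expect_equal(classification_loglik(dup, c(z, z), toy$st, toy$spec),
               2 * lc1, tolerance = 1e-10)
})

test_that("posterior membership follows Bayes theorem", {
  spec <- model_spec("compartment", "constant", 2, "shared")
  same <- group_structure(
    spec,
    groups = list(list(mu10 = 1e4, A = 0), list(mu10 = 1e4, A = 0)),
    pi = c(0.5, 0.5), sigma2 = 1,
    kinetics = c(k12 = 0.7, k21 = 0.25, k10 = 0.6))
  tr <- list(time = c(1, 8), log_hcg = c(9, 8))
  # identical groups: posterior equals the prior
  expect_equal(posterior_membership(tr, same, spec), c(0.5, 0.5))
  same$pi <- c(0.9, 0.1)
  expect_equal(posterior_membership(tr, same, spec), c(0.9, 0.1))

  # general case vs unnormalized raw-density brute force
  toy <- toy_structure(sigma2 = 2, pi = c(0.6, 0.4))
  tr2 <- list(time = c(2, 10), log_hcg = c(8.2, 7.0))
  raw <- vapply(1:2, function(g)
    toy$st$pi[g] * exp(log_density_group(tr2, g, toy$st, toy$spec)),
    numeric(1))
  expect_equal(posterior_membership(tr2, toy$st, toy$spec), raw / sum(raw),
               tolerance = 1e-10)
})

test_that("posterior rows sum to one across a whole cohort", {
  sc <- separated_scenario(40)
  coh <- simulate_cohort(sc, seed = 21)
  st <- kinclust:::.scenario_structure(sc)
  post <- e_step(coh, st, sc$spec)
  expect_equal(rowSums(post), rep(1, n_subjects(coh)), tolerance = 1e-12)
})

test_that("parameter counting follows the documented convention", {
  # unconstrained bi-exponential, 4 groups, shared variance: 16 + 1 + 3
  expect_identical(count_free_parameters(
    model_spec("biexp", n_groups = 4, variance = "shared")), 20L)
  # compartment, constant production, 4 groups, shared variance:
  # 3 kinetics + 4 mu10 + 3 production (zero in the lowest group) + 1 + 3
  expect_identical(count_free_parameters(
    model_spec("compartment", "constant", 4, "shared")), 14L)
  # 2 groups, per-group variance: 3 + 2 + 1 + 2 + 1
  expect_identical(count_free_parameters(
    model_spec("compartment", "constant", 2, "per_group")), 9L)
})

test_that("information criteria implement their closed forms", {
  expect_equal(information_criteria(0, 1, exp(2))$BIC, 2)
  expect_equal(information_criteria(-100, 5, 50)$AIC, 210)
  # with degenerate posteriors the classification and mixture likelihoods
  # coincide, hence ICL = BIC
  ic <- information_criteria(-250, 7, 100, loglik_c = -250)
  expect_equal(ic$ICL, ic$BIC)
})
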