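# Group-wise Gaussian likelihood on the log scale, the classification
# log-likelihood maximized by CEM, parameter counting and information
# criteria.
#
# Conditional on group membership the residuals of one subject are
# independent, so the group density of a trajectory is a multivariate
# Gaussian with diagonal covariance around the group's mean log-trajectory.

#' Group-structure parameter set
#'
#' Holds everything that defines the G latent groups: the kinetic constants
#' shared across groups (compartment model only), per-group mean-model
#' parameters, mixing weights and residual variance(s).  Cross-group
#' constraints of the compartment model are structural: `k12`, `k21`, `k10`
#' live in a single shared slot and the residual-production coefficient of
#' group 1 (the group with the lowest trajectory level) is fixed at zero.
#'
#' @param spec a [model_spec()].
#' @param groups list of G lists: `list(mu10=, A=)` for the compartment
#'   model or `list(c=, a=, c2=, a2=)` for the bi-exponential model,
#'   ordered by ascending trajectory level.
#' @param pi mixing weights, positive, summing to 1.
#' @param sigma2 residual variance: scalar (shared) or length-G vector.
#' @param kinetics named vector `c(k12=, k21=, k10=)` (compartment only).
#' @return an object of class `group_structure`.
#' @export
group_structure <- function(spec, groups, pi, sigma2, kinetics = NULL) {
  G <- spec$n_groups
  stopifnot(length(groups) == G, length(pi) == G, all(pi > 0),
            abs(sum(pi) - 1) < 1e-8)
  if (spec$variance == "per_group") stopifnot(length(sigma2) == G)
  else stopifnot(length(sigma2) == 1)
  stopifnot(all(sigma2 > 0))
  if (spec$mean_model == "compartment") {
    stopifnot(!is.null(kinetics), all(c("k12", "k21", "k10") %in% names(kinetics)))
    if (spec$production != "none" && groups[[1]]$A != 0)
      stop("residual production must be zero in the lowest group")
  }
  structure(list(G = G, kinetics = kinetics, groups = groups,
                 pi = as.numeric(pi), sigma2 = as.numeric(sigma2)),
            class = "group_structure")
}

# residual variance of group g
.sigma2_g <- function(structure, g) {
  if (length(structure$sigma2) == 1) structure$sigma2 else structure$sigma2[g]
}

# group-g parameter object for the mean model
.group_params <- function(structure, g, spec) {
  gp <- structure$groups[[g]]
  if (spec$mean_model == "compartment") {
    k <- structure$kinetics
    compartment_params(mu10 = gp$mu10, k12 = k[["k12"]], k21 = k[["k21"]],
                       k10 = k[["k10"]],
                       A = if (spec$production == "none") 0 else gp$A,
                       production = spec$production)
  } else {
    biexp_params(gp$c, gp$a, gp$c2, gp$a2)
  }
}

# mu1 of group g at arbitrary times, fast path (closed form with fallback)
.group_mu1 <- function(structure, g, times, spec) {
  if (spec$mean_model == "compartment") {
    k <- structure$kinetics
    gp <- structure$groups[[g]]
    .mu1_auto(gp$mu10, k[["k12"]], k[["k21"]], k[["k10"]],
              if (spec$production == "none") 0 else gp$A,
              spec$production, times)
  } else {
    biexp_predict(.group_params(structure, g, spec), times)
  }
}

# N x G matrix of per-subject log group densities log f_g(Y_i); -Inf where
# the group's mean trajectory is infeasible at the subject's times.
.loglik_matrix <- function(cohort, structure, spec) {
  G <- structure$G
  N <- n_subjects(cohort)
  tt <- cohort$data$time
  yy <- cohort$data$log_hcg
  m <- cohort$counts
  out <- matrix(-Inf, N, G)
  for (g in seq_len(G)) {
    mu <- tryCatch(.group_mu1(structure, g, tt, spec), error = function(e) NULL)
    if (is.null(mu)) next
    if (any(!is.finite(mu)) || any(mu <= 0)) {
      # infeasible only for the subjects whose times hit the bad region
      bad <- !is.finite(mu) | mu <= 0
      mu[bad] <- 1  # placeholder; those subjects get -Inf below
      r2 <- (yy - log(mu))^2
      ss <- rowsum(r2, cohort$row_subject, reorder = TRUE)[, 1]
      s2 <- .sigma2_g(structure, g)
      lg <- -0.5 * m * log(2 * pi * s2) - ss / (2 * s2)
      lg[rowsum(as.numeric(bad), cohort$row_subject, reorder = TRUE)[, 1] > 0] <- -Inf
      out[, g] <- lg
    } else {
      r2 <- (yy - log(mu))^2
      ss <- rowsum(r2, cohort$row_subject, reorder = TRUE)[, 1]
      s2 <- .sigma2_g(structure, g)
      out[, g] <- -0.5 * m * log(2 * pi * s2) - ss / (2 * s2)
    }
  }
  out
}

#' Log-density of one trajectory under one group
#'
#' The diagonal multivariate-Gaussian log-density of a subject's log-hCG
#' measurements around the group's mean log-trajectory.  Returns `-Inf`
#' when the group's mean trajectory is non-positive at any of the
#' subject's measurement times.
#'
#' @param trajectory a [get_trajectory()] object (or any list with `time`
#'   and `log_hcg`).
#' @param group group index g.
#' @param structure a [group_structure()].
#' @param spec the matching [model_spec()].
#' @return scalar `log f_g(Y_i; alpha_g)`.
#' @export
log_density_group <- function(trajectory, group, structure, spec) {
  mu <- tryCatch(.group_mu1(structure, group, trajectory$time, spec),
                 error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
  s2 <- .sigma2_g(structure, group)
  sum(-0.5 * log(2 * pi * s2) - (trajectory$log_hcg - log(mu))^2 / (2 * s2))
}

#' Classification log-likelihood
#'
#' The augmented log-likelihood of the data and the hard assignments,
#' `sum_i sum_g z_ig log(pi_g f_g(Y_i; alpha_g))`, the objective jointly
#' maximized by the CEM algorithm and used for its stopping rule.
#'
#' @param cohort a `cohort`.
#' @param assignment integer vector of group indices (one per subject).
#' @param structure a [group_structure()].
#' @param spec the matching [model_spec()].
#' @return scalar classification log-likelihood.
#' @export
classification_loglik <- function(cohort, assignment, structure, spec) {
  N <- n_subjects(cohort)
  stopifnot(length(assignment) == N,
            all(assignment >= 1), all(assignment <= structure$G))
  if (length(structure$sigma2) > 1 &&
      any(tabulate(assignment, structure$G) == 0))
    stop("degenerate group: empty group under per-group residual variances")
  lf <- .loglik_matrix(cohort, structure, spec)
  sum(log(structure$pi)[assignment] + lf[cbind(seq_len(N), assignment)])
}

# posterior matrix from a log-density matrix, log-sum-exp stabilized
.posterior_from_logf <- function(logf, pi) {
  lp <- sweep(logf, 2, log(pi), `+`)
  m <- apply(lp, 1, max)
  if (any(!is.finite(m)))
    stop("trajectory unexplainable by any group")
  w <- exp(lp - m)
  w / rowSums(w)
}

# observed-data (mixture) log-likelihood, log-sum-exp stabilized
.mixture_loglik <- function(logf, pi) {
  lp <- sweep(logf, 2, log(pi), `+`)
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Posterior group-membership probabilities of one trajectory
#'
#' Bayes-theorem posteriors `tau_g = pi_g f_g(Y) / sum_h pi_h f_h(Y)`,
#' computed with log-sum-exp stabilization.
#'
#' @inheritParams log_density_group
#' @return numeric vector of length G summing to 1.
#' @export
posterior_membership <- function(trajectory, structure, spec) {
  lf <- vapply(seq_len(structure$G),
               function(g) log_density_group(trajectory, g, structure, spec),
               numeric(1))
  drop(.posterior_from_logf(matrix(lf, 1), structure$pi))
}

#' Count free parameters of a model specification
#'
#' Single convention shared by all information criteria: mean-model
#' parameters after the cross-group constraints, plus 1 (shared) or G
#' (per-group) variance parameters, plus G - 1 mixing weights.
#' Compartment model: 3 shared kinetic constants + G initial
#' concentrations + (G - 1) production coefficients (zero in the lowest
#' group; none when production is `"none"`).  Bi-exponential model: 4 G
#' unconstrained mean parameters.
#'
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
count_free_parameters <- function(spec) {
  G <- spec$n_groups
  mean_k <- if (spec$mean_model == "biexp") {
    4L * G
  } else {
    3L + G + if (spec$production == "none") 0L else G - 1L
  }
  var_k <- if (spec$variance == "per_group") G else 1L
  as.integer(mean_k + var_k + (G - 1L))
}

#' Information criteria
#'
#' `AIC = -2 l + 2k`, `BIC = -2 l + k log(n)`, and
#' `ICL = -2 l_c + k log(n)`: the BIC penalty applied to the
#' classification log-likelihood (the hard-assignment analogue of the
#' integrated classification likelihood; identical to BIC when the
#' posteriors are degenerate).  `n` is the number of subjects, the
#' likelihood unit.
#'
#' @param loglik observed-data (mixture) log-likelihood.
#' @param k free-parameter count, see [count_free_parameters()].
#' @param n number of subjects.
#' @param loglik_c classification log-likelihood (defaults to `loglik`).
#' @return list with `AIC`, `BIC`, `ICL`.
#' @export
information_criteria <- function(loglik, k, n, loglik_c = loglik) {
  stopifnot(k >= 1, n >= 2)
  list(AIC = -2 * loglik + 2 * k,
       BIC = -2 * loglik + k * log(n),
       ICL = -2 * loglik_c + k * log(n))
}
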