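# Mean-trajectory models.
#
# Biological model: two-compartment kinetics with bolus input.  mu1 is the
# plasma concentration, mu2 the tissue concentration;
#   d mu1/dt = -(k12 + k10) mu1 + k21 mu2 + r(t)
#   d mu2/dt =   k12 mu1 - k21 mu2
# with mu1(0) = mu10, mu2(0) = 0 and residual production r(t) = 0, A, or A*t.
# Non-biological competitor: mu1(t) = c exp(a t) + c2 exp(a2 t), unconstrained.

#' Structural model specification
#'
#' @param mean_model `"compartment"` (two-compartment kinetics) or `"biexp"`
#'   (unconstrained bi-exponential).
#' @param production residual-production hypothesis for the compartment
#'   model: `"constant"` (r(t) = A), `"linear"` (r(t) = A t, A in
#'   IU/L/day^2), or `"none"`.  Ignored for `"biexp"`.
#' @param n_groups number of latent trajectory groups G.
#' @param variance `"shared"` (one residual variance) or `"per_group"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(mean_model = c("compartment", "biexp"),
                       production = c("constant", "linear", "none"),
                       n_groups = 4,
                       variance = c("shared", "per_group")) {
  mean_model <- match.arg(mean_model)
  production <- match.arg(production)
  variance <- match.arg(variance)
  n_groups <- as.integer(n_groups)
  stopifnot(n_groups >= 1)
  structure(list(mean_model = mean_model,
                 production = if (mean_model == "biexp") "none" else production,
                 n_groups = n_groups, variance = variance),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s, G = %d, %s variance\n", x$mean_model,
              if (x$mean_model == "compartment")
                paste0(" (production ", x$production, ")") else "",
              x$n_groups, x$variance))
  invisible(x)
}

#' Two-compartment kinetic parameters
#'
#' @param mu10 initial plasma concentration (IU/L), `mu1(0)`.
#' @param k12,k21,k10 plasma-to-tissue, tissue-to-plasma and elimination
#'   rate constants (per day); all non-negative.
#' @param A residual production coefficient: IU/L/day for constant
#'   production, IU/L/day^2 for time-proportional production.
#' @param production one of `"none"`, `"constant"`, `"linear"`.
#' @return an object of class `compartment_params`.
#' @export
compartment_params <- function(mu10, k12, k21, k10, A = 0,
                               production = c("none", "constant", "linear")) {
  production <- match.arg(production)
  stopifnot(mu10 > 0, k12 >= 0, k21 >= 0, k10 >= 0, A >= 0)
  structure(list(mu10 = mu10, k12 = k12, k21 = k21, k10 = k10,
                 A = if (production == "none") 0 else A,
                 production = production),
            class = "compartment_params")
}

#' Bi-exponential parameters (non-biological model)
#'
#' No sign constraints; the predicted concentration may be negative for
#' some parameter values, in which case log-scale evaluation fails (see
#' [mean_log_trajectory()]).
#'
#' @param c,a,c2,a2 coefficients of `c exp(a t) + c2 exp(a2 t)`.
#' @return an object of class `biexp_params`.
#' @export
biexp_params <- function(c, a, c2, a2) {
  structure(list(c = c, a = a, c2 = c2, a2 = a2), class = "biexp_params")
}

# Closed-form plasma concentration of the two-compartment system.
# Homogeneous part: eigen-decomposition of the 2x2 transfer matrix (real,
# distinct eigenvalues whenever the discriminant is positive).  Constant
# production adds the steady state (A/k10, k12 A / (k21 k10)); linear
# production adds a particular solution affine in t.  Errors instruct
# falling back to the numeric path for the degenerate cases.
.mu1_closed <- function(mu10, k12, k21, k10, A, production, times) {
  if (production == "none") A <- 0
  if (k21 <= 0) {
    # no back-transfer: mu1 decouples, mu1' = -q mu1 + r(t)
    q <- k12 + k10
    if (q <= 0) {
      return(switch(production,
                    none = rep(mu10, length(times)),
                    constant = mu10 + A * times,
                    linear = mu10 + A * times^2 / 2))
    }
    return(switch(production,
                  none = mu10 * exp(-q * times),
                  constant = A / q + (mu10 - A / q) * exp(-q * times),
                  linear = (mu10 + A / q^2) * exp(-q * times) +
                    (A / q) * (times - 1 / q)))
  }
  tr <- -(k12 + k21 + k10)
  dt_ <- k21 * k10
  disc <- tr^2 - 4 * dt_
  if (disc <= 1e-12 * max(tr^2, 1))
    stop("repeated eigenvalues in compartment system; use the numeric solver")
  sq <- sqrt(disc)
  lam1 <- (tr + sq) / 2
  lam2 <- (tr - sq) / 2
  v1 <- c(k21, lam1 + k12 + k10)
  v2 <- c(k21, lam2 + k12 + k10)
  if (production != "none" && A > 0 && k10 <= 0)
    stop("production with no elimination has no steady state; use the numeric solver")
  # particular solution p(t) and its value at 0
  if (production == "constant" && A > 0) {
    p0 <- c(A / k10, k12 * A / (k21 * k10))
    p1_t <- rep(p0[1], length(times))
  } else if (production == "linear" && A > 0) {
    u <- c(A / k10, k12 * A / (k21 * k10))
    M <- matrix(c(-(k12 + k10), k21, k12, -k21), 2, 2, byrow = TRUE)
    v <- solve(M, u)
    p0 <- v
    p1_t <- u[1] * times + v[1]
  } else {
    p0 <- c(0, 0)
    p1_t <- 0
  }
  w0 <- c(mu10, 0) - p0
  alpha <- solve(cbind(v1, v2), w0)
  as.numeric(alpha[1] * v1[1] * exp(lam1 * times) +
               alpha[2] * v2[1] * exp(lam2 * times) + p1_t)
}

# Numeric LSODA solution.
.mu1_numeric <- function(mu10, k12, k21, k10, A, production, times,
                         abs_tol = 1e-6) {
  if (production == "none") A <- 0
  tt <- sort(unique(c(0, times)))
  if (length(tt) < 2) return(rep(mu10, length(times)))
  rhs <- function(t, y, p) {
    r <- switch(production, none = 0, constant = A, linear = A * t)
    list(c(-(k12 + k10) * y[1] + k21 * y[2] + r,
           k12 * y[1] - k21 * y[2]))
  }
  out <- deSolve::lsoda(c(mu1 = mu10, mu2 = 0), times = tt, func = rhs,
                        parms = NULL, atol = abs_tol, rtol = 1e-9)
  if (attr(out, "istate")[1] < 0)
    stop("LSODA failed for parameters mu10=", mu10, " k12=", k12, " k21=", k21,
         " k10=", k10, " A=", A)
  unname(out[match(times, tt), "mu1"])
}

# Fast path used inside the likelihood: closed form, numeric fallback.
.mu1_auto <- function(mu10, k12, k21, k10, A, production, times,
                      abs_tol = 1e-6) {
  tryCatch(.mu1_closed(mu10, k12, k21, k10, A, production, times),
           error = function(e)
             .mu1_numeric(mu10, k12, k21, k10, A, production, times, abs_tol))
}

#' Solve the two-compartment system numerically (LSODA)
#'
#' Integrates the kinetic ODE system with [deSolve::lsoda()], which switches
#' automatically between Adams and BDF methods depending on stiffness.
#'
#' @param params a [compartment_params()] object.
#' @param times non-negative, sorted evaluation times (days).
#' @param abs_tol absolute error tolerance of the solver (default `1e-6`).
#' @return plasma concentrations `mu1(times)`.
#' @export
solve_compartment_numeric <- function(params, times, abs_tol = 1e-6) {
  stopifnot(inherits(params, "compartment_params"), all(times >= 0))
  .mu1_numeric(params$mu10, params$k12, params$k21, params$k10, params$A,
               params$production, times, abs_tol)
}

#' Solve the two-compartment system in closed form
#'
#' Analytic solution via the eigen-decomposition of the transfer matrix:
#' the homogeneous part is a sum of two exponentials; constant production
#' adds the steady state `A/k10`; time-proportional production adds a
#' particular solution affine in time.  Preferred inside the likelihood for
#' speed; equivalence with the numeric path is enforced by tests.
#'
#' @inheritParams solve_compartment_numeric
#' @return plasma concentrations `mu1(times)`.
#' @export
solve_compartment_closed_form <- function(params, times) {
  stopifnot(inherits(params, "compartment_params"), all(times >= 0))
  .mu1_closed(params$mu10, params$k12, params$k21, params$k10, params$A,
              params$production, times)
}

#' Evaluate the bi-exponential model
#'
#' @param params a [biexp_params()] object.
#' @param times evaluation times (days).
#' @return concentrations `c exp(a t) + c2 exp(a2 t)`.
#' @export
biexp_predict <- function(params, times) {
  stopifnot(inherits(params, "biexp_params"))
  params$c * exp(params$a * times) + params$c2 * exp(params$a2 * times)
}

#' Mean log-trajectory
#'
#' Returns `ln mu1(t)`, the mean of the Gaussian measurement model on the
#' log scale.  Errors with "invalid mean trajectory" when the underlying
#' concentration is non-positive at any requested time (possible for
#' unconstrained bi-exponential parameters); the M-step treats such points
#' as infeasible.
#'
#' @param params a [compartment_params()] or [biexp_params()] object.
#' @param times evaluation times (days).
#' @param method for compartment parameters, `"closed_form"` (default) or
#'   `"numeric"`.
#' @param abs_tol numeric-solver tolerance.
#' @return log-scale mean trajectory at `times`.
#' @export
mean_log_trajectory <- function(params, times, method = c("closed_form", "numeric"),
                                abs_tol = 1e-6) {
  method <- match.arg(method)
  mu <- if (inherits(params, "biexp_params")) {
    biexp_predict(params, times)
  } else if (method == "numeric") {
    solve_compartment_numeric(params, times, abs_tol)
  } else {
    .mu1_auto(params$mu10, params$k12, params$k21, params$k10, params$A,
              params$production, times, abs_tol)
  }
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("invalid mean trajectory: non-positive concentration at some times")
  log(mu)
}
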