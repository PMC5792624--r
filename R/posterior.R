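#' Prior settings for the hierarchical fatality model
#'
#' Fixed effects (intercept and coefficients) get independent
#' Normal(0, `beta_var`) priors; with the default variance of 1000 these are
#' effectively uninformative on the log-risk scale. The random-effect
#' precision tau gets a Gamma(`tau_shape`, `tau_rate`) prior, equivalently
#' log(tau) ~ log-gamma with the same shape and inverse scale; the default
#' (1, 0.0005) is very diffuse.
#'
#' @param beta_var Prior variance of each fixed effect.
#' @param tau_shape,tau_rate Shape and rate (inverse scale) of the precision
#'   prior.
#' @return List of class `rr_prior`.
#' @export
prior_control <- function(beta_var = 1000, tau_shape = 1, tau_rate = 0.0005) {
  stopifnot(beta_var > 0, tau_shape > 0, tau_rate > 0)
  structure(list(beta_var = beta_var, tau_shape = tau_shape,
                 tau_rate = tau_rate), class = "rr_prior")
}

#' Log density of log(tau) under the log-gamma prior
#'
#' If tau ~ Gamma(shape, rate) then L = log(tau) has density
#' rate^shape / Gamma(shape) * exp(shape * L - rate * exp(L)); the two
#' parameterisations are the same distribution up to the Jacobian.
#'
#' @param log_tau Value of log(tau).
#' @param shape,rate Gamma parameters.
#' @return Log density (normalised).
#' @export
dloggamma <- function(log_tau, shape = 1, rate = 0.0005) {
  shape * log(rate) - lgamma(shape) + shape * log_tau - rate * exp(log_tau)
}

#' Joint log posterior of the Poisson-lognormal fatality model
#'
#' The model: y_n ~ Poisson(f_n) with
#' log f_n = offset_n + beta0 + x_n' beta + delta_n, unit effects
#' delta_n ~ Normal(0, 1/tau), and log(tau) ~ log-gamma(shape, rate). The
#' offset is log population, so exp(beta0 + x'beta + delta) is a per-capita
#' fatality risk. Returns the fully normalised log density of
#' (beta0, beta, delta, log tau) given the data (likelihood including the
#' log y! term, plus all prior terms).
#'
#' @param beta0 Intercept.
#' @param beta Fixed-effect vector aligned with the columns of `X` (may be
#'   length 0 for an intercept-only model).
#' @param delta Unit random effects, length n.
#' @param log_tau Log precision of the unit effects.
#' @param X n x p covariate matrix.
#' @param offset Log-exposure vector (log population).
#' @param y Non-negative integer response vector.
#' @param prior A [prior_control()].
#' @return Scalar log density; `-Inf` only for structurally impossible
#'   states (e.g. an infinite Poisson mean), otherwise finite or an error.
#' @export
log_posterior <- function(beta0, beta, delta, log_tau, X, offset, y,
                          prior = prior_control()) {
  params <- c(beta0, beta, delta, log_tau)
  if (any(!is.finite(params))) stop("non-finite parameter value")
  if (length(beta)) {
    eta <- offset + beta0 + drop(as.matrix(X) %*% beta) + delta
  } else {
    eta <- offset + beta0 + delta
  }
  f <- exp(eta)
  ll <- sum(y * eta - f - lgamma(y + 1))
  tau <- exp(log_tau)
  lp_delta <- sum(stats::dnorm(delta, 0, sqrt(1 / tau), log = TRUE))
  lp_tau <- dloggamma(log_tau, prior$tau_shape, prior$tau_rate)
  lp_beta <- sum(stats::dnorm(c(beta0, beta), 0, sqrt(prior$beta_var),
                              log = TRUE))
  out <- ll + lp_delta + lp_tau + lp_beta
  if (is.nan(out)) stop("non-finite intermediate in log posterior")
  out
}

#' Posterior mode of the fixed effects with unit effects pinned at zero
#'
#' Maximises [log_posterior()] over (beta0, beta) with delta = 0 and tau held
#' at a large fixed value, i.e. the penalised Poisson log-linear fit. Used
#' for sampler initialisation checks and as a bridge to maximum-likelihood
#' fits (with the diffuse default prior the mode is numerically the MLE).
#'
#' @inheritParams log_posterior
#' @param log_tau Fixed log precision (default log(1e8): delta pinned).
#' @return Named vector `(Intercept)` + coefficient estimates.
#' @export
posterior_mode_beta <- function(X, offset, y, prior = prior_control(),
                                log_tau = log(1e8)) {
  X <- as.matrix(X)
  n <- length(y)
  start <- c(log(max(mean(y / exp(offset)), 1e-12)), rep(0, ncol(X)))
  negll <- function(b)
    -log_posterior(b[1], b[-1], rep(0, n), log_tau, X, offset, y, prior)
  gr <- function(b) {
    eta <- offset + b[1] + drop(X %*% b[-1])
    r <- y - exp(eta)
    -(c(sum(r), drop(crossprod(X, r))) - b / prior$beta_var)
  }
  fit <- stats::optim(start, negll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  stats::setNames(fit$par, c("(Intercept)", colnames(X)))
}

#' Classify posterior significance from equal-tailed credible intervals
#'
#' A coefficient is flagged at the 95% level when zero lies outside the
#' central 95% interval (2.5%-97.5% quantiles), and at the 90% level when
#' zero lies outside the 5%-95% interval. A 95% flag implies the 90% flag.
#'
#' @param summary A data.frame with columns `q2.5`, `q5`, `q95`, `q97.5`
#'   (as produced by [summary.fatality_fit()]).
#' @return The data.frame with logical `sig90` and `sig95` columns and a
#'   `signif` factor in `none`/`90%`/`95%`.
#' @export
classify_significance <- function(summary) {
  stopifnot(all(c("q2.5", "q5", "q95", "q97.5") %in% names(summary)))
  sig95 <- summary$q2.5 > 0 | summary$q97.5 < 0
  sig90 <- summary$q5 > 0 | summary$q95 < 0
  sig90 <- sig90 | sig95
  summary$sig90 <- sig90
  summary$sig95 <- sig95
  summary$signif <- ifelse(sig95, "95%", ifelse(sig90, "90%", "none"))
  summary
}
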