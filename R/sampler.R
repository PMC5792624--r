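#' Sampler settings for the hierarchical fatality model
#'
#' @param chains Number of independent chains (default 4).
#' @param warmup Adaptation iterations per chain, discarded (default 2000).
#' @param draws Retained iterations per chain (default 2000).
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param rhat_limit,ess_limit Convergence-flag thresholds for fixed effects.
#' @return List of class `rr_sampler_control`.
#' @export
sampler_control <- function(chains = 4, warmup = 2000, draws = 2000, seed = 1L,
                            rhat_limit = 1.05, ess_limit = 400) {
  stopifnot(chains >= 1, warmup >= 10, draws >= 10)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_limit = rhat_limit, ess_limit = ess_limit),
            class = "rr_sampler_control")
}

#' Fit the hierarchical Poisson-lognormal model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the posterior defined by
#' [log_posterior()]. The chain state is (beta, eta, tau) where
#' eta_n = log f_n; the unit effects are recovered as
#' delta_n = eta_n - offset_n - x_n'beta. Each iteration performs:
#' a vectorised per-unit adaptive random-walk Metropolis update of eta
#' (the eta_n are conditionally independent given beta and tau); an exact
#' conjugate Gaussian draw of the fixed effects given eta and tau (given eta
#' the model is a linear regression of eta - offset on the covariates with
#' Normal(0, 1/tau) errors); and an exact conjugate Gamma draw of tau.
#' Proposal scales adapt toward a 44% acceptance rate during warmup only, so
#' the retained draws come from a fixed-kernel Markov chain.
#'
#' @param X n x p covariate matrix (no intercept column; may have 0 columns).
#' @param offset Log-exposure (log population) vector.
#' @param y Non-negative integer response vector.
#' @param control A [sampler_control()].
#' @param prior A [prior_control()].
#' @param design Optional list carrying `unit_id` and model metadata, stored
#'   on the result.
#' @return Object of class `fatality_fit`.
#' @export
fit_posterior <- function(X, offset, y, control = sampler_control(),
                          prior = prior_control(), design = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(offset) != n) stop("dimension mismatch")
  if (n < p + 3) stop("need at least p + 3 units to fit ", p, " covariates")
  if (any(y < 0) || any(y != round(y))) stop("response must be counts")
  Xi <- cbind("(Intercept)" = 1, X)
  p1 <- p + 1L
  XtX <- crossprod(Xi)
  P0 <- diag(1 / prior$beta_var, p1)

  # Poisson GLM mode for initialisation (offset model, no random effects)
  init_beta <- tryCatch(
    unname(stats::coef(suppressWarnings(
      stats::glm.fit(Xi, y, family = stats::poisson(),
                     offset = offset)))),
    error = function(e) c(log(max(mean(y / exp(offset)), 1e-12)), rep(0, p)))
  init_beta[!is.finite(init_beta)] <- 0

  total <- control$warmup + control$draws
  beta_draws <- vector("list", control$chains)
  tau_draws <- vector("list", control$chains)
  delta_sum <- matrix(0, control$chains, n)
  delta_sq <- matrix(0, control$chains, n)
  accept <- numeric(control$chains)

  withr_seed(control$seed, {
    for (ch in seq_len(control$chains)) {
      beta <- init_beta + stats::rnorm(p1, 0, 0.05)
      eta <- log(pmax(y, 0.5)) + stats::rnorm(n, 0, 0.05)
      delta <- eta - offset - drop(Xi %*% beta)
      tau <- 1 / max(stats::var(delta), 0.01)
      step <- rep(0.5, n)
      bmat <- matrix(NA_real_, control$draws, p1)
      tvec <- numeric(control$draws)
      acc_n <- 0
      for (it in seq_len(total)) {
        # 1. eta: component-wise adaptive RW Metropolis (vectorised)
        mu <- offset + drop(Xi %*% beta)
        prop <- eta + step * stats::rnorm(n)
        logr <- y * (prop - eta) - (exp(prop) - exp(eta)) -
          0.5 * tau * ((prop - mu)^2 - (eta - mu)^2)
        acc <- log(stats::runif(n)) < logr
        eta[acc] <- prop[acc]
        if (it <= control$warmup) {
          gain <- min(0.5, 3 / sqrt(it))
          step <- step * exp(gain * (acc - 0.44))
          step <- pmin(pmax(step, 1e-4), 10)
        } else {
          acc_n <- acc_n + mean(acc)
        }
        # 2. beta | eta, tau: exact conjugate Gaussian
        A <- tau * XtX + P0
        R <- chol(A)
        m <- backsolve(R, forwardsolve(t(R), tau * crossprod(Xi, eta - offset)))
        beta <- drop(m + backsolve(R, stats::rnorm(p1)))
        # 3. tau | delta: exact conjugate Gamma
        delta <- eta - offset - drop(Xi %*% beta)
        tau <- stats::rgamma(1, prior$tau_shape + n / 2,
                             prior$tau_rate + sum(delta^2) / 2)
        if (it > control$warmup) {
          k <- it - control$warmup
          bmat[k, ] <- beta
          tvec[k] <- tau
          delta_sum[ch, ] <- delta_sum[ch, ] + delta
          delta_sq[ch, ] <- delta_sq[ch, ] + delta^2
        }
      }
      beta_draws[[ch]] <- bmat
      tau_draws[[ch]] <- tvec
      accept[ch] <- acc_n / control$draws
    }
  })

  par_names <- c("(Intercept)", colnames(X))
  pooled_beta <- do.call(rbind, beta_draws)
  colnames(pooled_beta) <- par_names
  pooled_tau <- unlist(tau_draws)

  qs <- c(0.025, 0.05, 0.5, 0.95, 0.975)
  summarize <- function(x) {
    q <- stats::quantile(x, qs, names = FALSE)
    c(mean = mean(x), sd = stats::sd(x),
      q2.5 = q[1], q5 = q[2], q50 = q[3], q95 = q[4], q97.5 = q[5])
  }
  sm <- t(apply(pooled_beta, 2, summarize))
  sigma_delta <- 1 / sqrt(pooled_tau)
  sm <- rbind(sm, tau_delta = summarize(pooled_tau),
              sigma_delta = summarize(sigma_delta))
  summary_df <- data.frame(parameter = rownames(sm), sm,
                           row.names = NULL, check.names = FALSE)

  chain_arrays <- lapply(seq_len(p1), function(j)
    sapply(beta_draws, function(b) b[, j]))
  rhat <- vapply(chain_arrays, split_rhat, numeric(1))
  ess <- vapply(chain_arrays, split_ess, numeric(1))
  names(rhat) <- names(ess) <- par_names
  converged <- all(rhat < control$rhat_limit, na.rm = TRUE) &&
    all(ess > control$ess_limit, na.rm = TRUE)

  delta_mean <- colSums(delta_sum) / (control$chains * control$draws)
  delta_sd <- sqrt(pmax(colSums(delta_sq) / (control$chains * control$draws) -
                          delta_mean^2, 0))

  summary_df <- classify_significance(summary_df)
  structure(list(summary = summary_df,
                 draws = list(beta = pooled_beta, tau = pooled_tau,
                              by_chain = beta_draws, tau_by_chain = tau_draws),
                 delta = list(mean = delta_mean, sd = delta_sd),
                 diagnostics = list(rhat = rhat, ess = ess,
                                    converged = converged,
                                    accept_eta = mean(accept)),
                 y = y, X = X, offset = offset,
                 control = control, prior = prior, design = design),
            class = "fatality_fit")
}

# split-chain R-hat (each chain halved; between/within variance ratio)
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size from split chains (Geyer initial-monotone pairs)
split_ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sp <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  m <- ncol(sp); nn <- nrow(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  varplus <- (nn - 1) / nn * W + nn * stats::var(colMeans(sp)) / nn
  lag_max <- min(nn - 2, 250)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(sp[, j], lag.max = lag_max, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / varplus
  # sum consecutive pairs while positive and non-increasing
  npair <- floor(length(rho) / 2)
  s <- 0; prev <- Inf
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
  }
  m * nn / (1 + 2 * s)
}
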