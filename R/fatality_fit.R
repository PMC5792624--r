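#' Fit the state-level fatality model
#'
#' High-level fitting interface: builds the design for the requested model
#' specification from a study frame and exposure table, then samples the
#' hierarchical Poisson-lognormal posterior with [fit_posterior()]. The
#' response is the rounded three-year mean of on-road deaths; log population
#' enters as an offset so coefficients act on per-capita fatality risk.
#'
#' @param frame Filtered `study_frame` (islands removed).
#' @param exposure Exposure table from [build_exposure()].
#' @param model Model specification id (1-4, see [model_spec()]) or a spec
#'   list.
#' @param control A [sampler_control()].
#' @param prior A [prior_control()].
#' @param density_scale Divisor for the density covariate (see
#'   [build_design()]).
#' @return A `fatality_fit` (see [fit_posterior()]).
#' @export
fit_fatality_model <- function(frame, exposure, model = 4,
                               control = sampler_control(),
                               prior = prior_control(),
                               density_scale = 1e4) {
  spec <- if (is.list(model)) model else model_spec(model)
  d <- build_design(frame, exposure, spec, density_scale = density_scale)
  fit <- fit_posterior(d$X, d$offset, d$y, control = control, prior = prior,
                       design = list(spec = spec, unit_id = d$unit_id,
                                     density_scale = density_scale))
  fit
}

#' @export
print.fatality_fit <- function(x, ...) {
  cat("Hierarchical Poisson-lognormal fatality model\n")
  if (!is.null(x$design$spec))
    cat("  model", x$design$spec$model_id, "-")
  cat(" ", length(x$y), "units,", ncol(x$X), "covariates,",
      x$control$chains, "chains x", x$control$draws, "draws\n")
  fe <- x$summary[seq_len(ncol(x$X) + 1), ]
  est <- stats::setNames(round(fe$mean, 3), fe$parameter)
  print(est)
  if (!x$diagnostics$converged)
    cat("  warning: convergence flag not met (max R-hat ",
        round(max(x$diagnostics$rhat, na.rm = TRUE), 3), ", min ESS ",
        round(min(x$diagnostics$ess, na.rm = TRUE)), ")\n", sep = "")
  invisible(x)
}

#' Posterior summary table
#'
#' One row per parameter (intercept, coefficients, the random-effect
#' precision tau and SD sigma) with posterior mean, SD, the 2.5/5/50/95/97.5
#' percent quantiles, and credible-interval significance flags.
#'
#' @param object A `fatality_fit`.
#' @param ... Unused.
#' @return data.frame (invisible component of the printed summary).
#' @export
summary.fatality_fit <- function(object, ...) {
  out <- object$summary
  attr(out, "diagnostics") <- object$diagnostics
  class(out) <- c("summary.fatality_fit", "data.frame")
  out
}

#' @export
print.summary.fatality_fit <- function(x, ...) {
  df <- as.data.frame(x)
  df$mark <- ifelse(df$sig95, "**", ifelse(df$sig90, "*", ""))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df[, c("parameter", "mean", "sd", "q2.5", "q50", "q97.5", "mark")],
        row.names = FALSE)
  cat("'*' zero outside 90% BCI, '**' outside 95% BCI\n")
  dg <- attr(x, "diagnostics")
  cat("max split R-hat:", round(max(dg$rhat, na.rm = TRUE), 3),
      " min ESS:", round(min(dg$ess, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
coef.fatality_fit <- function(object, ...) {
  fe <- object$summary[seq_len(ncol(object$X) + 1), ]
  stats::setNames(fe$mean, fe$parameter)
}

#' Posterior expected fatality counts
#'
#' For the fitted units (`newdata = NULL`) the expectation includes the
#' posterior-mean unit effect delta_n; for new design data delta is set to
#' its population mean of zero.
#'
#' @param object A `fatality_fit`.
#' @param newdata Optional list with elements `X` and `offset`.
#' @param type `"response"` (expected counts, default) or `"link"` (log
#'   scale).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.fatality_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  b <- coef(object)
  if (is.null(newdata)) {
    eta <- object$offset + b[1] +
      (if (ncol(object$X)) drop(object$X %*% b[-1]) else 0) +
      object$delta$mean
  } else {
    Xn <- as.matrix(newdata$X)
    eta <- newdata$offset + b[1] +
      (if (ncol(Xn)) drop(Xn %*% b[-1]) else 0)
  }
  if (type == "link") eta else exp(eta)
}

#' @export
fitted.fatality_fit <- function(object, ...) predict(object)

#' Pearson residuals at the posterior mean
#' @param object A `fatality_fit`.
#' @param ... Unused.
#' @export
residuals.fatality_fit <- function(object, ...) {
  f <- predict(object)
  (object$y - f) / sqrt(f)
}

#' Posterior predictive simulation of yearly death counts
#'
#' Draws parameter vectors (beta, tau) from the stored posterior draws, a
#' fresh delta ~ N(0, 1/tau) per unit, and Poisson counts around the implied
#' expectation — i.e. new hypothetical units sharing the fitted covariates.
#'
#' @param object A `fatality_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns, one simulated count vector each.
#' @export
simulate.fatality_fit <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    n <- length(object$y)
    idx <- sample.int(nrow(object$draws$beta), nsim, replace = TRUE)
    out <- sapply(idx, function(i) {
      b <- object$draws$beta[i, ]
      tau <- object$draws$tau[i]
      delta <- stats::rnorm(n, 0, 1 / sqrt(tau))
      eta <- object$offset + b[1] +
        (if (ncol(object$X)) drop(object$X %*% b[-1]) else 0) + delta
      stats::rpois(n, exp(eta))
    })
    as.data.frame(out)
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' Plot a fatality-model fit
#'
#' `which = "coef"` draws posterior means with 95% credible bars for the
#' fixed effects; `which = "trace"` draws per-chain trace plots of the
#' intercept and first coefficients.
#'
#' @param x A `fatality_fit`.
#' @param which `"coef"` or `"trace"`.
#' @param ... Passed to the underlying graphics calls.
#' @export
plot.fatality_fit <- function(x, which = c("coef", "trace"), ...) {
  which <- match.arg(which)
  fe <- x$summary[seq_len(ncol(x$X) + 1), ]
  if (which == "coef") {
    idx <- seq_len(nrow(fe))
    graphics::plot(fe$mean, idx, xlim = range(fe$q2.5, fe$q97.5),
                   yaxt = "n", xlab = "posterior mean (95% BCI)", ylab = "",
                   pch = 19, ...)
    graphics::segments(fe$q2.5, idx, fe$q97.5, idx)
    graphics::abline(v = 0, lty = 2)
    graphics::axis(2, at = idx, labels = fe$parameter, las = 1, cex.axis = 0.7)
  } else {
    k <- min(4, ncol(x$draws$beta))
    graphics::par(mfrow = c(k, 1), mar = c(2, 4, 1, 1))
    for (j in seq_len(k)) {
      chains <- x$draws$by_chain
      graphics::plot(chains[[1]][, j], type = "l",
                     ylab = colnames(x$draws$beta)[j],
                     ylim = range(sapply(chains, function(b) range(b[, j]))),
                     ...)
      if (length(chains) > 1)
        for (ch in 2:length(chains))
          graphics::lines(chains[[ch]][, j], col = ch)
    }
  }
  invisible(x)
}

#' Fit the four-model sequence plus the access-walk sensitivity grid
#'
#' Fits models 1-4 on the main exposure (1 km access walk) and re-fits the
#' final model at each value of `walk_grid`, rebuilding the exposure table
#' each time. Returns the fits and a wide coefficient table (posterior mean,
#' SD and significance marks per model column).
#'
#' @param frame Filtered `study_frame`.
#' @param bins Long commute-bin data.frame (see [load_commute_bins()]).
#' @param reps Per-bin representative distances.
#' @param control A [sampler_control()].
#' @param prior A [prior_control()].
#' @param walk_grid Access-walk sensitivity values (km per PT commuter).
#' @param density_scale Passed to [build_design()].
#' @return List with `fits` (models 1-4), `sensitivity` (final model per
#'   walk value), and `table` (wide data.frame).
#' @export
fit_model_sequence <- function(frame, bins,
                               reps = bin_representative_distances(),
                               control = sampler_control(),
                               prior = prior_control(),
                               walk_grid = c(0, 1, 1.5),
                               density_scale = 1e4) {
  main_exposure <- build_exposure(bins, reps, walk_per_trip = 1)
  fits <- lapply(1:4, function(m)
    fit_fatality_model(frame, main_exposure, m, control, prior,
                       density_scale))
  names(fits) <- paste0("model", 1:4)
  sens <- lapply(walk_grid, function(w) {
    expw <- build_exposure(bins, reps, walk_per_trip = w)
    fit_fatality_model(frame, expw, 4, control, prior, density_scale)
  })
  names(sens) <- paste0("walk", walk_grid)

  all_params <- c("(Intercept)",
                  colnames(build_design(frame, main_exposure, model_spec(4),
                                        density_scale)$X),
                  "tau_delta", "sigma_delta")
  col_block <- function(fit, label) {
    sm <- fit$summary
    i <- match(all_params, sm$parameter)
    out <- data.frame(mean = sm$mean[i], sd = sm$sd[i],
                      sig = sm$signif[i])
    names(out) <- paste0(label, "_", names(out))
    out
  }
  table <- data.frame(parameter = all_params, stringsAsFactors = FALSE)
  for (m in 1:4) table <- cbind(table, col_block(fits[[m]], paste0("m", m)))
  for (w in seq_along(walk_grid))
    table <- cbind(table, col_block(sens[[w]],
                                    paste0("sens_walk", walk_grid[w])))
  list(fits = fits, sensitivity = sens, table = table)
}
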