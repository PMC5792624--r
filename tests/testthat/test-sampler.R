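sim_design <- function(n = 33, seed = 1, beta0 = -9,
                       beta = c(`ln(walk)` = -0.3, `ln(2W)` = 0.4,
                                `ln(bus)` = 0.1),
                       sigma_delta = 0.3) {
  tp <- true_params(beta0 = beta0, beta = beta, sigma_delta = sigma_delta,
                    n_units = n, seed = seed)
  sim <- synth_study(tp)
  t <- sim$truth
  list(X = t$X, offset = t$offset, y = as.integer(round(rowMeans(
    cbind(sim$frame$deaths_2010, sim$frame$deaths_2011,
          sim$frame$deaths_2012)))),
    beta_true = c(beta0, unname(beta[colnames(t$X)])))
}

test_that("identical seeds give identical fits", {
  d <- sim_design(n = 20, seed = 3)
  f1 <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 7, warmup = 200,
                                                    draws = 200))
  f2 <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 7, warmup = 200,
                                                    draws = 200))
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws$beta, f2$draws$beta)
  f3 <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 8, warmup = 200,
                                                    draws = 200))
  expect_false(identical(f1$summary$mean, f3$summary$mean))
})

test_that("planted coefficients are recovered within 3 posterior SDs", {
  d <- sim_design(n = 200, seed = 12)
  fit <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 4))
  sm <- fit$summary[1:4, ]
  expect_true(all(abs(sm$mean - d$beta_true) < 3 * sm$sd))
  # sign recovery under a strong signal
  expect_equal(sign(sm$mean[-1]), sign(d$beta_true[-1]))
})

test_that("intercept posterior matches a dense-grid integration oracle", {
  # beta0-only model with the precision pinned at tau0 via a sharp prior
  set.seed(20)
  n <- 6
  offset <- log(round(runif(n, 5e4, 5e5)))
  sigma0 <- 0.3; tau0 <- 1 / sigma0^2
  delta <- rnorm(n, 0, sigma0)
  y <- rpois(n, exp(offset - 9 + delta))
  X <- matrix(numeric(0), n, 0)

  # oracle: marginal likelihood of beta0 by 2-d quadrature (grid x grid)
  b_grid <- seq(-11, -7, length.out = 801)
  d_grid <- seq(-1.6, 1.6, length.out = 401)
  log_marg <- vapply(b_grid, function(b0) {
    per_unit <- vapply(seq_len(n), function(i) {
      eta <- offset[i] + b0 + d_grid
      terms <- y[i] * eta - exp(eta) - lgamma(y[i] + 1) +
        dnorm(d_grid, 0, sigma0, log = TRUE)
      m <- max(terms)
      m + log(sum(exp(terms - m))) + log(d_grid[2] - d_grid[1])
    }, numeric(1))
    sum(per_unit) + dnorm(b0, 0, sqrt(1000), log = TRUE)
  }, numeric(1))
  w <- exp(log_marg - max(log_marg))
  oracle_mean <- sum(b_grid * w) / sum(w)

  pinned <- prior_control(tau_shape = tau0 * 1e8, tau_rate = 1e8)
  fit <- fit_posterior(X, offset, y, fast_ctrl(seed = 2, warmup = 500,
                                               draws = 2000), prior = pinned)
  expect_lt(abs(fit$summary$mean[1] - oracle_mean), 0.02)
})

test_that("scaling the exposure shifts only the intercept by -log c", {
  d <- sim_design(n = 60, seed = 30)
  f1 <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 5, draws = 1000))
  f2 <- fit_posterior(d$X, d$offset + log(10), d$y,
                      fast_ctrl(seed = 6, draws = 1000))
  se <- function(f, j) f$summary$sd[j] / sqrt(max(f$diagnostics$ess[j], 50))
  shift <- f1$summary$mean[1] - f2$summary$mean[1]
  tol <- 2 * sqrt(se(f1, 1)^2 + se(f2, 1)^2) + 0.005
  expect_lt(abs(shift - log(10)), tol)
  # slope coefficients essentially unchanged
  expect_lt(max(abs(f1$summary$mean[2:4] - f2$summary$mean[2:4])),
            6 * max(f1$summary$sd[2:4] / sqrt(200)))
})

test_that("posterior SDs shrink as the number of units grows", {
  small <- sim_design(n = 33, seed = 41)
  big <- sim_design(n = 330, seed = 42)
  fs <- fit_posterior(small$X, small$offset, small$y, fast_ctrl(seed = 1))
  fb <- fit_posterior(big$X, big$offset, big$y, fast_ctrl(seed = 1))
  expect_true(all(fb$summary$sd[1:4] < fs$summary$sd[1:4]))
})

test_that("with delta pinned the posterior mean approaches the Poisson MLE", {
  d <- sim_design(n = 50, seed = 55, sigma_delta = 0)
  pinned <- prior_control(tau_shape = 1e8 * 1e4, tau_rate = 1e8)  # tau ~ 1e4
  fit <- fit_posterior(d$X, d$offset, d$y,
                       fast_ctrl(seed = 9, draws = 1500), prior = pinned)
  mle <- newton_poisson(d$X, d$offset, d$y)
  # counts are in the thousands: the GLM sampling SD dwarfs any MCMC error
  expect_lt(max(abs(fit$summary$mean[1:4] - mle)), 0.05)
})

test_that("short chains trip the convergence flag, long chains satisfy it", {
  d <- sim_design(n = 33, seed = 61)
  short <- fit_posterior(d$X, d$offset, d$y,
                         sampler_control(chains = 2, warmup = 30, draws = 20,
                                         seed = 1))
  expect_false(short$diagnostics$converged)
  long <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 1, draws = 1500))
  expect_true(long$diagnostics$converged)
  expect_true(all(long$diagnostics$rhat < 1.05, na.rm = TRUE))
})

test_that("model interface: methods on fatality_fit behave coherently", {
  sim <- synth_study(true_params(n_units = 25, seed = 70))
  fit <- fit_fatality_model(sim$frame, sim$exposure, model = 1,
                            control = fast_ctrl(seed = 3, warmup = 300,
                                                draws = 400))
  expect_s3_class(fit, "fatality_fit")
  expect_named(coef(fit), c("(Intercept)", "ln(bus)", "ln(IPT)", "ln(car)",
                            "ln(walk)", "ln(cycle)", "ln(2W)"))
  f <- predict(fit)
  expect_true(all(f > 0))
  expect_equal(predict(fit, type = "link"), log(f))
  r <- residuals(fit)
  expect_equal(r, (fit$y - f) / sqrt(f))
  # fitted values with the unit effect track the data closely
  expect_gt(cor(log(f), log(fit$y + 0.5)), 0.95)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(25L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  sm <- summary(fit)
  expect_true(all(c("parameter", "mean", "sd", "signif") %in% names(sm)))
  expect_output(print(fit), "Hierarchical Poisson-lognormal")
  expect_output(print(sm), "BCI")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "trace"))
})

test_that("quantile columns are monotone and tau summaries positive", {
  d <- sim_design(n = 20, seed = 80)
  fit <- fit_posterior(d$X, d$offset, d$y, fast_ctrl(seed = 2, warmup = 200,
                                                     draws = 300))
  sm <- fit$summary
  expect_true(all(sm$q2.5 <= sm$q5 & sm$q5 <= sm$q50 &
                    sm$q50 <= sm$q95 & sm$q95 <= sm$q97.5))
  expect_true(all(sm[sm$parameter %in% c("tau_delta", "sigma_delta"),
                     c("q2.5", "q50", "q97.5")] > 0))
})

test_that("the four-model sequence emits the full sensitivity table", {
  sim <- synth_study(true_params(n_units = 20, seed = 90))
  seqfit <- fit_model_sequence(sim$frame, sim$bins,
                               control = fast_ctrl(seed = 1, warmup = 150,
                                                   draws = 150))
  expect_named(seqfit$fits, paste0("model", 1:4))
  expect_named(seqfit$sensitivity, c("walk0", "walk1", "walk1.5"))
  tb <- seqfit$table
  expect_equal(sum(grepl("_mean$", names(tb))), 7)  # 4 models + 3 sensitivity
  # model-1 column is blank for the control covariates
  expect_true(all(is.na(tb$m1_mean[tb$parameter %in%
                                     c("ln(diesel)", "ln(nh)", "prop_urban",
                                       "density")])))
  expect_false(anyNA(tb$m4_mean))
})
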