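# fixtures are built in code at test time; nothing binary is stored

# minimal valid units data.frame (not yet a study_frame)
make_units_df <- function(n = 5, islands = 0, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    unit_id = sprintf("S%02d", seq_len(n)),
    name = paste("State", seq_len(n)),
    is_island = rep(c(FALSE, TRUE), c(n - islands, islands)),
    population = round(runif(n, 3e5, 5e7)),
    stringsAsFactors = FALSE)
  df$urban_population <- round(df$population * runif(n, 0.1, 0.9))
  df$built_up_area_km2 <- round(runif(n, 50, 5000), 1)
  df$nh_length_km <- round(runif(n, 20, 5000), 1)
  df$diesel_kt <- round(runif(n, 50, 7000), 1)
  for (y in 2010:2012) df[[paste0("deaths_", y)]] <- rpois(n, 2000)
  df
}

write_units_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# single-unit long commute table from a named list mode -> c(bin = workers)
toy_bins <- function(entries, unit_id = "T1") {
  rows <- list()
  for (md in names(entries)) {
    w <- entries[[md]]
    for (b in names(w)) {
      rows[[length(rows) + 1]] <- data.frame(
        unit_id = unit_id, mode = md, bin_label = b, workers = w[[b]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# exhaustive k-means oracle: minimum WSS over all assignments of n points
# into k clusters (centroid = member mean); independent of the package path
exhaustive_wss <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 9)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < k) next
    w <- 0
    for (j in seq_len(k)) {
      pts <- x[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      w <- w + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, w)
  }
  best
}

# independent Newton/IRLS oracle for the Poisson log-linear model with offset
newton_poisson <- function(X, offset, y, tol = 1e-12, max_iter = 100) {
  Xi <- cbind(1, X)
  b <- c(log(max(mean(y / exp(offset)), 1e-12)), rep(0, ncol(X)))
  for (i in seq_len(max_iter)) {
    eta <- offset + drop(Xi %*% b)
    mu <- exp(eta)
    g <- drop(crossprod(Xi, y - mu))
    H <- crossprod(Xi * mu, Xi)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# brute-force term-by-term log posterior oracle (explicit loops, no reuse of
# package internals beyond the prior settings)
oracle_log_posterior <- function(beta0, beta, delta, log_tau, X, offset, y,
                                 beta_var = 1000, shape = 1, rate = 0.0005) {
  n <- length(y)
  tau <- exp(log_tau)
  total <- 0
  for (i in seq_len(n)) {
    eta_i <- offset[i] + beta0 + delta[i]
    if (length(beta)) eta_i <- eta_i + sum(X[i, ] * beta)
    total <- total + y[i] * eta_i - exp(eta_i) - lgamma(y[i] + 1)
    total <- total + dnorm(delta[i], 0, 1 / sqrt(tau), log = TRUE)
  }
  total <- total + shape * log(rate) - lgamma(shape) +
    shape * log_tau - rate * tau
  for (b in c(beta0, beta))
    total <- total + dnorm(b, 0, sqrt(beta_var), log = TRUE)
  total
}

# random Poisson regression problem for posterior-density checks
rand_problem <- function(n = 8, p = 3, seed = 5) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), offset = log(runif(n, 1e5, 1e7)),
       y = rpois(n, 40))
}

# small fast sampler settings for tests
fast_ctrl <- function(seed = 1, chains = 2, warmup = 400, draws = 600)
  sampler_control(chains = chains, warmup = warmup, draws = draws, seed = seed)
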