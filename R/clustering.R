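#' Seeded k-means clustering of mode-share vectors
#'
#' Groups areal units with similar commute mode-share profiles. Lloyd's
#' algorithm is run to convergence from `restarts` k-means++ initialisations
#' and the lowest within-cluster sum of squares (WSS) solution is returned;
#' the whole procedure is deterministic given `seed`. Shares are clustered
#' unstandardised: they are already commensurate proportions.
#'
#' @param shares Numeric matrix, units x modes (rows should sum to 1).
#' @param k Number of clusters, `1 <= k <= nrow(shares)`.
#' @param seed Integer RNG seed.
#' @param restarts Number of seeded initialisations (default 50).
#' @param init Optional list of initial centroid matrices; when supplied these
#'   are used as extra restarts (used internally to warm-start the k curve).
#' @return Object of class `share_kmeans`: list with `k`, `assignments`
#'   (named integer vector), `centroids`, `wss`, `per_cluster_wss`,
#'   `wss_trace` (per-Lloyd-iteration WSS of the winning restart).
#' @export
kmeans_shares <- function(shares, k, seed = 1L, restarts = 50L, init = NULL) {
  shares <- as.matrix(shares)
  n <- nrow(shares)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds number of units (", n, ")")
  best <- NULL
  run_one <- function(centers) {
    fit <- lloyd(shares, centers)
    if (is.null(best) || fit$wss < best$wss) best <<- fit
  }
  withr_seed(seed, {
    for (r in seq_len(restarts)) run_one(kmeanspp_init(shares, k))
    for (cen in init) run_one(fixup_centers(shares, cen))
  })
  structure(list(k = k,
                 assignments = stats::setNames(best$cluster,
                                               rownames(shares)),
                 centroids = best$centers,
                 wss = best$wss,
                 per_cluster_wss = best$per_cluster_wss,
                 wss_trace = best$trace),
            class = "share_kmeans")
}

#' @export
print.share_kmeans <- function(x, ...) {
  cat("k-means on mode shares: k =", x$k,
      " total WSS =", format(x$wss, digits = 6), "\n")
  cat("cluster sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

# run body under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# squared Euclidean distances of rows of x to rows of centers (n x k)
sqdist <- function(x, centers) {
  n <- nrow(x); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  d2
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
# centres with probability proportional to squared distance to nearest centre
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(n, 1)
      else idx[j] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

fixup_centers <- function(x, centers) {
  centers <- as.matrix(centers)
  if (ncol(centers) != ncol(x)) stop("initial centers have wrong dimension")
  centers
}

# Lloyd's algorithm with per-iteration WSS trace; empty clusters are re-seeded
# on the point farthest from its centre
lloyd <- function(x, centers, max_iter = 100L) {
  k <- nrow(centers)
  trace <- numeric(0)
  cluster <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(x, centers)
    new_cluster <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_cluster == j)) {
        # re-seed an empty cluster on the worst-fit point of a cluster that
        # can spare one (ties broken by index, so duplicates still split)
        sizes <- tabulate(new_cluster, k)
        cand <- which(sizes[new_cluster] > 1)
        if (!length(cand)) cand <- seq_along(new_cluster)
        nearest <- d2[cbind(seq_along(new_cluster), new_cluster)]
        far <- cand[which.max(nearest[cand])]
        new_cluster[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[new_cluster == j, , drop = FALSE])
    wss_now <- sum((x - centers[new_cluster, , drop = FALSE])^2)
    trace <- c(trace, wss_now)
    if (identical(new_cluster, cluster) && it > 1) break
    cluster <- new_cluster
  }
  per <- vapply(seq_len(k), function(j)
    sum((x[cluster == j, , drop = FALSE] -
           matrix(centers[j, ], sum(cluster == j), ncol(x), byrow = TRUE))^2),
    numeric(1))
  list(cluster = cluster, centers = centers,
       wss = sum(per), per_cluster_wss = per, trace = trace)
}

#' Choose the number of clusters from the WSS elbow
#'
#' Computes the best-of-restarts WSS for each candidate k and returns the
#' smallest k at which adding one more cluster no longer buys a meaningful
#' WSS reduction. The reduction is measured relative to the total sum of
#' squares (WSS at k = 1), so "meaningful" has a fixed yardstick across k;
#' the full curve is returned for visual elbow inspection. Each k+1 search is
#' warm-started from the best k-solution plus the worst-fit point, which
#' guarantees a non-increasing curve.
#'
#' @inheritParams kmeans_shares
#' @param k_range Candidate k values (default 1:10, capped at n).
#' @param threshold Relative reduction (fraction of total SS) below which the
#'   elbow is declared (default 0.01).
#' @return List with `k` (chosen), `wss` (named numeric curve), `fits`
#'   (the `share_kmeans` objects).
#' @export
choose_k <- function(shares, k_range = 1:10, seed = 1L, restarts = 50L,
                     threshold = 0.01) {
  shares <- as.matrix(shares)
  if (!length(k_range)) stop("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range <= nrow(shares)]
  fits <- list(); wss <- numeric(0)
  prev <- NULL
  for (k in k_range) {
    init <- NULL
    if (!is.null(prev)) {
      # augment previous centroids with the worst-fit point
      d2 <- sqdist(shares, prev$centroids)
      nearest <- apply(d2, 1, min)
      extra <- shares[which.max(nearest), , drop = FALSE]
      cen <- rbind(prev$centroids, extra)
      if (nrow(cen) == k) init <- list(cen)
    }
    fit <- kmeans_shares(shares, k, seed = seed + k, restarts = restarts,
                         init = init)
    fits[[as.character(k)]] <- fit
    wss[as.character(k)] <- fit$wss
    prev <- fit
  }
  tss <- wss[1]
  if (is.na(tss)) tss <- max(wss)
  chosen <- k_range[length(k_range)]
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (wss[i] <= 1e-12 * max(tss, 1e-300)) { chosen <- k; break }
    if (i < length(k_range)) {
      drop_rel <- (wss[i] - wss[i + 1]) / tss
      if (drop_rel < threshold) { chosen <- k; break }
    }
  }
  list(k = chosen, wss = wss, fits = fits)
}

#' Per-cluster mode-share profile and median fatality rate
#'
#' @param fit `share_kmeans` result.
#' @param shares The share matrix that was clustered.
#' @param rates Named per-unit fatality rates (per 100,000/year), aligned to
#'   the rows of `shares`.
#' @return data.frame: one row per cluster with size, mean share per mode,
#'   and `median_rate`.
#' @export
cluster_profile <- function(fit, shares, rates) {
  shares <- as.matrix(shares)
  if (is.null(colnames(shares)))
    colnames(shares) <- paste0("m", seq_len(ncol(shares)))
  stopifnot(length(fit$assignments) == nrow(shares),
            length(rates) == nrow(shares))
  out <- lapply(seq_len(fit$k), function(j) {
    sel <- fit$assignments == j
    prof <- colMeans(shares[sel, , drop = FALSE])
    row <- data.frame(cluster = j, n_units = sum(sel))
    for (md in colnames(shares)) row[[paste0("share_", md)]] <- prof[[md]]
    row$median_rate <- stats::median(rates[sel])
    row
  })
  do.call(rbind, out)
}

#' Pearson correlation between mode shares and fatality rates
#'
#' @param shares units x modes share matrix.
#' @param rates per-unit fatality rates aligned to rows.
#' @return Named numeric vector of Pearson r per mode; `NA` where a share
#'   column is constant (correlation undefined).
#' @export
share_rate_correlation <- function(shares, rates) {
  shares <- as.matrix(shares)
  if (nrow(shares) < 3) stop("need at least 3 units")
  vapply(colnames(shares), function(md) {
    x <- shares[, md]
    if (stats::sd(x) == 0 || stats::sd(rates) == 0) return(NA_real_)
    stats::cor(x, rates)
  }, numeric(1))
}
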