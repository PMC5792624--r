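#' Ground-truth parameters for synthetic studies
#'
#' Defaults emulate the study's conditions: 33 areal units, the final-model
#' coefficient means as true effects, and a lognormal extra-Poisson
#' variation of SD 0.3 on the log scale (a typical overdispersion level for
#' state-level injury counts).
#'
#' @param beta0 True intercept (log per-capita risk scale).
#' @param beta Named true coefficients; names must be design column names
#'   (e.g. `"ln(walk)"`, `"prop_urban"`).
#' @param sigma_delta SD of the unit random effects (>= 0).
#' @param n_units Number of areal units (>= 5).
#' @param seed Integer seed.
#' @return List of class `rr_true_params`.
#' @export
true_params <- function(beta0 = -9.178,
                        beta = c("ln(bus)" = 0.066, "ln(IPT)" = -0.234,
                                 "ln(car)" = 0.263, "ln(walk)" = -0.355,
                                 "ln(cycle)" = -0.200, "ln(2W)" = 0.390,
                                 "ln(diesel)" = 0.264, "ln(nh)" = -0.146,
                                 prop_urban = -0.832, density = 0.039),
                        sigma_delta = 0.3, n_units = 33, seed = 1L) {
  stopifnot(sigma_delta >= 0, n_units >= 5)
  structure(list(beta0 = beta0, beta = beta, sigma_delta = sigma_delta,
                 n_units = as.integer(n_units), seed = as.integer(seed)),
            class = "rr_true_params")
}

# draw one Dirichlet vector via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# typical worker mode split used when no centroids are planted
default_mode_split <- function() {
  c(walk = 0.28, cycle = 0.17, `2W` = 0.13, car = 0.04, IPT = 0.06,
    bus = 0.19, train = 0.13)
}

#' Generate synthetic binned commute counts
#'
#' Per unit: total "other workers" drawn log-uniform over [1e4, 5e6]; the
#' mode split drawn from a Dirichlet centred on the unit's assigned centroid
#' (round-robin over `cluster_centroids` when given, a common typical split
#' otherwise); within each mode, workers fall into distance bins by a
#' multinomial whose probabilities decay with the representative bin
#' distance at a mode-specific scale. Walking is confined to bins up to
#' 6-10 km and cycling up to 21-30 km (structural zeros beyond). Every mode
#' is guaranteed at least one commuter so logged distances exist downstream.
#'
#' @param n_units Number of areal units.
#' @param seed Integer seed (byte-identical output on rerun).
#' @param cluster_centroids Optional k x 7 matrix of worker mode splits
#'   (columns named by [rr_modes()]); units are assigned round-robin and the
#'   true assignment is attached as attribute `cluster`.
#' @param concentration Dirichlet concentration around the centroid
#'   (larger = tighter clusters; default 300).
#' @return Long data.frame `unit_id`, `mode`, `bin_label`, `workers`.
#' @export
gen_commute_bins <- function(n_units, seed = 1L, cluster_centroids = NULL,
                             concentration = 300) {
  modes <- rr_modes(); bins <- rr_bins()
  cap <- rr_mode_bin_cap()
  reps <- bin_representative_distances()
  decay_scale <- c(walk = 2, cycle = 5, `2W` = 10, car = 12, IPT = 8,
                   bus = 15, train = 25)
  if (!is.null(cluster_centroids)) {
    cluster_centroids <- as.matrix(cluster_centroids)
    if (is.null(colnames(cluster_centroids)))
      colnames(cluster_centroids) <- modes
    assignment <- rep_len(seq_len(nrow(cluster_centroids)), n_units)
  } else {
    assignment <- rep_len(1L, n_units)
  }
  out <- withr_seed(seed, {
    rows <- list()
    for (i in seq_len(n_units)) {
      uid <- sprintf("U%02d", i)
      total <- round(exp(stats::runif(1, log(1e4), log(5e6))))
      centre <- if (is.null(cluster_centroids)) default_mode_split()
                else cluster_centroids[assignment[i], modes]
      split <- rdirichlet1(pmax(centre, 1e-3) * concentration)
      workers_mode <- drop(stats::rmultinom(1, total, split))
      workers_mode <- pmax(workers_mode, 1L)
      names(workers_mode) <- modes
      for (md in modes) {
        ok <- seq_len(cap[md])
        pr <- exp(-reps[bins][ok] / decay_scale[md])
        w <- drop(stats::rmultinom(1, workers_mode[md], pr))
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, mode = md, bin_label = bins[ok], workers = w,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "cluster") <- stats::setNames(assignment,
                                          sprintf("U%02d", seq_len(n_units)))
  out
}

# infer a model spec from the names of a true coefficient vector
spec_from_beta <- function(beta) {
  nm <- names(beta)
  logs <- sub("^ln\\((.*)\\)$", "\\1", nm[grepl("^ln\\(", nm)])
  list(model_id = NA, log_covariates = logs,
       linear_covariates = nm[!grepl("^ln\\(", nm)],
       offset_field = "population")
}

#' Generate a synthetic study frame by forward simulation
#'
#' Populations are drawn log-uniform over [2.4e5, 2e8] and auxiliary
#' covariates within the magnitudes of the real state-level data (diesel
#' 48-7483 thousand tonnes, national-highway length 15-5874 km, urbanisation
#' 10-98%, built-up density 258-226,066 persons/km^2, all log-uniform except
#' urbanisation). Unit effects delta_n ~ Normal(0, sigma_delta^2); the
#' expected count is f_n = population_n * exp(beta0 + x_n'beta + delta_n)
#' and three yearly death counts are drawn independently as Poisson(f_n),
#' emulating the three-year averaging pathway.
#'
#' @param params A [true_params()].
#' @param exposure Exposure table from [build_exposure()] providing the
#'   mode-distance covariates (one row per unit).
#' @param density_scale Passed to [build_design()].
#' @return A `study_frame`; the realised `delta`, expected counts `f` and
#'   design are attached as attribute `truth`.
#' @export
gen_units <- function(params, exposure, density_scale = 1e4) {
  n <- nrow(exposure)
  frame <- withr_seed(params$seed, {
    population <- round(exp(stats::runif(n, log(243247), log(199812341))))
    density <- exp(stats::runif(n, log(258), log(226066)))
    df <- data.frame(
      unit_id = exposure$unit_id,
      name = paste("Unit", exposure$unit_id),
      is_island = FALSE,
      population = population,
      urban_population = round(stats::runif(n, 0.10, 0.98) * population),
      built_up_area_km2 = population / density,
      nh_length_km = exp(stats::runif(n, log(15), log(5874))),
      diesel_kt = exp(stats::runif(n, log(48), log(7483))),
      deaths_2010 = 0L, deaths_2011 = 0L, deaths_2012 = 0L,
      stringsAsFactors = FALSE)
    frame <- new_study_frame(df, 2010:2012)

    spec <- spec_from_beta(params$beta)
    d <- build_design(frame, exposure, spec, density_scale = density_scale)
    beta <- params$beta[colnames(d$X)]
    if (anyNA(beta)) stop("true beta names do not match design columns")
    delta <- stats::rnorm(n, 0, params$sigma_delta)
    log_f <- d$offset + params$beta0 + drop(d$X %*% beta) + delta
    if (any(log_f > 25))
      stop("expected counts overflow (log f > 25); parameters out of range")
    f <- exp(log_f)
    for (y in 2010:2012)
      frame[[paste0("deaths_", y)]] <- stats::rpois(n, f)
    attr(frame, "truth") <- list(params = params, delta = delta, f = f,
                                 X = d$X, offset = d$offset)
    frame
  })
  frame
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [gen_commute_bins()], [build_exposure()] and
#' [gen_units()] with a single seed.
#'
#' @param params A [true_params()].
#' @param cluster_centroids Passed to [gen_commute_bins()].
#' @param walk_per_trip PT access-walk km used in the exposure build.
#' @param ... Passed to [gen_commute_bins()].
#' @return List with `bins`, `exposure`, `frame`, `truth`.
#' @export
synth_study <- function(params = true_params(), cluster_centroids = NULL,
                        walk_per_trip = 1, ...) {
  bins <- gen_commute_bins(params$n_units, seed = params$seed,
                           cluster_centroids = cluster_centroids, ...)
  exposure <- build_exposure(bins, walk_per_trip = walk_per_trip)
  frame <- gen_units(params, exposure)
  list(bins = bins, exposure = exposure, frame = frame,
       truth = attr(frame, "truth"))
}

#' Write a synthetic study to CSV in the canonical schemas
#'
#' Emits `units.csv`, `commute_bins.csv` and `truth.json` (planted
#' parameters) into `dir`, ready for [load_area_units()],
#' [load_commute_bins()] and [run_pipeline()].
#'
#' @param dir Output directory (created if needed).
#' @param params A [true_params()].
#' @param n_islands Number of extra island units appended (flagged
#'   `is_island = TRUE`, default 2) so the exclusion rule is exercised.
#' @param ... Passed to [synth_study()].
#' @return Invisibly, the list of file paths.
#' @export
write_synthetic_study <- function(dir, params = true_params(),
                                  n_islands = 2, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  total_units <- params$n_units + n_islands
  params_all <- params
  params_all$n_units <- as.integer(total_units)
  sim <- synth_study(params_all, ...)
  frame <- sim$frame
  if (n_islands > 0) {
    island_rows <- seq(total_units - n_islands + 1, total_units)
    frame$is_island[island_rows] <- TRUE
  }
  units_path <- file.path(dir, "units.csv")
  bins_path <- file.path(dir, "commute_bins.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(as.data.frame(frame), units_path, row.names = FALSE)
  utils::write.csv(sim$bins, bins_path, row.names = FALSE)
  jsonlite::write_json(
    list(beta0 = params$beta0, beta = as.list(params$beta),
         sigma_delta = params$sigma_delta, n_units = params$n_units,
         n_islands = n_islands, seed = params$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(units = units_path, bins = bins_path, truth = truth_path))
}
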