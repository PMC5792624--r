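#' Default pipeline configuration
#'
#' @param units_csv,commute_csv Input file paths.
#' @param out_dir Output artifact directory.
#' @param years Analysis years.
#' @param walk_per_trip Main-analysis PT access-walk km.
#' @param walk_grid Sensitivity grid for the final model.
#' @param open_bin_km Representative distance of the open `>50` bin.
#' @param bin_overrides Optional named per-bin distances.
#' @param k_range,k_threshold,cluster_restarts Clustering settings.
#' @param seed Master seed (clustering and sampling are derived from it).
#' @param sampler List with `chains`, `warmup`, `draws`.
#' @param step_pp,n_steps,exponent_precision Scenario settings.
#' @param density_scale Density covariate divisor.
#' @param write_draws Also write pooled posterior draws of the final model
#'   as CSV.
#' @return Configuration list.
#' @export
pipeline_config <- function(units_csv, commute_csv, out_dir,
                            years = 2010:2012, walk_per_trip = 1,
                            walk_grid = c(0, 1, 1.5), open_bin_km = 60,
                            bin_overrides = NULL, k_range = 1:10,
                            k_threshold = 0.01, cluster_restarts = 50,
                            seed = 1L,
                            sampler = list(chains = 4, warmup = 2000,
                                           draws = 2000),
                            step_pp = 0.5, n_steps = 10,
                            exponent_precision = "rounded",
                            density_scale = 1e4, write_draws = FALSE) {
  as.list(environment())
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Ingest -> exposure -> clustering -> model sequence -> scenarios, writing
#' every module's output plus a machine-readable manifest into the artifact
#' directory. Any stage failure aborts with the stage named.
#'
#' @param config List from [pipeline_config()] or [read_pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)

  frame <- stage("ingest", {
    fr <- load_area_units(config$units_csv, config$years)
    report <- validate_study_frame(fr)
    fr <- filter_units(fr)
    utils::write.csv(as.data.frame(fr), outp("units_validated.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(report, list(n_after_island_filter = nrow(fr))),
                         outp("validation.json"), auto_unbox = TRUE)
    fr
  })

  exposure <- stage("exposure", {
    bins <- load_commute_bins(config$commute_csv)
    reps <- bin_representative_distances(config$bin_overrides,
                                         config$open_bin_km)
    ex <- build_exposure(bins, reps, config$walk_per_trip)
    missing <- setdiff(frame$unit_id, ex$unit_id)
    if (length(missing))
      stop("no commute data for unit(s): ", paste(missing, collapse = ", "))
    utils::write.csv(ex, outp("exposure.csv"), row.names = FALSE)
    ex
  })

  clust <- stage("cluster", {
    ex <- exposure[match(frame$unit_id, exposure$unit_id), , drop = FALSE]
    shares <- share_matrix(ex)
    sel <- choose_k(shares, config$k_range, seed = config$seed,
                    restarts = config$cluster_restarts,
                    threshold = config$k_threshold)
    fit <- sel$fits[[as.character(sel$k)]]
    rates <- fatality_summary(frame)$rate_per_100k
    profiles <- cluster_profile(fit, shares, rates)
    utils::write.csv(data.frame(unit_id = names(fit$assignments),
                                cluster = unname(fit$assignments)),
                     outp("clusters.csv"), row.names = FALSE)
    utils::write.csv(profiles, outp("cluster_profiles.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(k = sel$k, wss = as.list(sel$wss),
                              correlations = as.list(
                                share_rate_correlation(shares, rates))),
                         outp("wss.json"), auto_unbox = TRUE, digits = NA)
    list(fit = fit, profiles = profiles, k = sel$k)
  })

  models <- stage("fit", {
    bins <- load_commute_bins(config$commute_csv)
    reps <- bin_representative_distances(config$bin_overrides,
                                         config$open_bin_km)
    ctrl <- sampler_control(chains = config$sampler$chains,
                            warmup = config$sampler$warmup,
                            draws = config$sampler$draws,
                            seed = config$seed)
    seq_fit <- fit_model_sequence(frame, bins, reps, control = ctrl,
                                  walk_grid = config$walk_grid,
                                  density_scale = config$density_scale)
    utils::write.csv(seq_fit$table, outp("table3.csv"), row.names = FALSE)
    diag <- lapply(seq_fit$fits, function(f)
      list(rhat = as.list(f$diagnostics$rhat),
           ess = as.list(f$diagnostics$ess),
           converged = f$diagnostics$converged))
    jsonlite::write_json(diag, outp("diagnostics.json"), auto_unbox = TRUE,
                         digits = NA)
    if (isTRUE(config$write_draws))
      utils::write.csv(as.data.frame(seq_fit$fits$model4$draws$beta),
                       outp("posterior_draws_model4.csv"), row.names = FALSE)
    seq_fit
  })

  stage("scenarios", {
    curves <- run_scenarios(clust$profiles, step_pp = config$step_pp,
                            n_steps = config$n_steps,
                            exponents = scenario_exponents(
                              config$exponent_precision))
    utils::write.csv(curves, outp("rr_curves.csv"), row.names = FALSE)
  })

  manifest <- list(
    inputs = list(
      units_csv = unname(tools::md5sum(config$units_csv)),
      commute_csv = unname(tools::md5sum(config$commute_csv))),
    config = config[setdiff(names(config), c("units_csv", "commute_csv",
                                             "out_dir"))],
    chosen_k = clust$k,
    versions = list(r = as.character(getRversion()),
                    roadrisk = as.character(
                      utils::packageVersion("roadrisk"))),
    outputs = union(list.files(config$out_dir), "manifest.json"))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
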