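#' Model specifications for the fatality regression sequence
#'
#' Four nested specifications, from minimally to maximally controlled:
#' Model 1 has only the six on-road commute-distance covariates (logged);
#' Model 2 adds logged annual diesel consumption (a proxy for freight and
#' taxi traffic); Model 3 adds logged national-highway length; Model 4 adds
#' the proportion of population that is urban and the built-up population
#' density, both untransformed. Train vehicular distance is never a
#' covariate (only its access walking, folded into the walk distance, is).
#'
#' @param model_id 1, 2, 3 or 4.
#' @return List with `model_id`, `log_covariates`, `linear_covariates`,
#'   `offset_field`.
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% 1:4) stop("model_id must be 1, 2, 3 or 4")
  logc <- c("bus", "IPT", "car", "walk", "cycle", "2W")
  linc <- character(0)
  if (model_id >= 2) logc <- c(logc, "diesel")
  if (model_id >= 3) logc <- c(logc, "nh")
  if (model_id >= 4) linc <- c("prop_urban", "density")
  list(model_id = model_id, log_covariates = logc, linear_covariates = linc,
       offset_field = "population")
}

#' Build the regression design from a study frame and exposure table
#'
#' Assembles the response (rounded three-year mean on-road deaths), the
#' log-population offset, and the covariate matrix in specification order.
#' Mode distances come from the exposure table (walk already includes the PT
#' access-walk kilometres); density is population over built-up area, divided
#' by `density_scale` (default 10,000, i.e. tens of thousands of persons per
#' square kilometre) to keep the raw-scale coefficient readable.
#'
#' @param frame Filtered `study_frame`.
#' @param exposure Exposure table from [build_exposure()].
#' @param spec A [model_spec()].
#' @param density_scale Divisor applied to persons per km^2.
#' @param subtract_rail Passed to [average_annual_fatalities()].
#' @return List with `X` (n x p covariate matrix, no intercept column),
#'   `offset` (log population), `y` (integer response), `unit_id`.
#' @export
build_design <- function(frame, exposure, spec = model_spec(4),
                         density_scale = 1e4, subtract_rail = TRUE) {
  idx <- match(frame$unit_id, exposure$unit_id)
  if (anyNA(idx))
    stop("exposure table missing unit(s): ",
         paste(frame$unit_id[is.na(idx)], collapse = ", "))
  exposure <- exposure[idx, , drop = FALSE]

  covariate_value <- function(name) {
    switch(name,
      bus = exposure$dist_bus, IPT = exposure$dist_IPT,
      car = exposure$dist_car, walk = exposure$dist_walk,
      cycle = exposure$dist_cycle, `2W` = exposure$`dist_2W`,
      diesel = frame$diesel_kt, nh = frame$nh_length_km,
      prop_urban = frame$urban_population / frame$population,
      density = frame$population / frame$built_up_area_km2 / density_scale,
      stop("unknown covariate: ", name))
  }

  cols <- list()
  for (nm in spec$log_covariates) {
    v <- covariate_value(nm)
    bad <- which(!(v > 0))
    if (length(bad))
      stop("covariate '", nm, "' must be > 0 to be logged; offending unit(s): ",
           paste(frame$unit_id[bad], collapse = ", "))
    cols[[paste0("ln(", nm, ")")]] <- log(v)
  }
  for (nm in spec$linear_covariates) cols[[nm]] <- covariate_value(nm)
  X <- do.call(cbind, cols)
  rownames(X) <- frame$unit_id

  md <- vapply(seq_len(nrow(frame)), function(i)
    average_annual_fatalities(frame[i, , drop = FALSE],
                              attr(frame, "years"), subtract_rail),
    numeric(1))
  if (any(md < 0)) stop("negative mean deaths after railway-crossing subtraction")
  list(X = X, offset = log(frame$population), y = as.integer(round(md)),
       unit_id = frame$unit_id)
}
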