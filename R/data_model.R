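#' Load areal-unit records from CSV
#'
#' Reads one row per areal unit (state or union territory) with population,
#' urban population, built-up area, national-highway length, annual diesel
#' consumption and yearly road-death counts, and validates the schema.
#' Optional `rail_deaths_<year>` columns carry deaths at railway crossings,
#' which are subtracted from the road-death counts downstream (they arise
#' where trains and on-road modes interact and are excluded from the on-road
#' fatality burden).
#'
#' @param path Path to a UTF-8 CSV with header. Required columns:
#'   `unit_id`, `name`, `is_island`, `population`, `urban_population`,
#'   `built_up_area_km2`, `nh_length_km`, `diesel_kt`, and `deaths_<year>` for
#'   every analysis year. Optional: `rail_deaths_<year>`.
#' @param years Integer vector of analysis years (default `2010:2012`).
#' @return A `study_frame`: a data.frame with one row per unit, death counts
#'   in list-columns-free wide form, and a `years` attribute.
#' @export
load_area_units <- function(path, years = 2010:2012) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("unit_id", "name", "is_island", "population", "urban_population",
                "built_up_area_km2", "nh_length_km", "diesel_kt",
                paste0("deaths_", years))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  dup <- df$unit_id[duplicated(df$unit_id)]
  if (length(dup))
    stop("duplicate unit_id: ", paste(unique(dup), collapse = ", "))

  num_cols <- setdiff(required, c("unit_id", "name", "is_island"))
  num_cols <- c(num_cols, grep("^rail_deaths_", names(df), value = TRUE))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]]))
    if (length(bad))
      stop("non-numeric or missing value in column '", cl,
           "' at row(s) with unit_id: ",
           paste(df$unit_id[bad], collapse = ", "))
    df[[cl]] <- v
  }
  df$is_island <- as.logical(df$is_island)
  if (anyNA(df$is_island)) stop("is_island must be TRUE/FALSE (or 0/1)")

  frame <- new_study_frame(df, years)
  validate_study_frame(frame)
  frame
}

new_study_frame <- function(df, years) {
  structure(df, years = as.integer(years),
            class = c("study_frame", "data.frame"))
}

#' @export
print.study_frame <- function(x, ...) {
  cat("Study frame:", nrow(x), "areal units, years",
      paste(range(attr(x, "years")), collapse = "-"), "\n")
  NextMethod()
  invisible(x)
}

#' Validate a study frame
#'
#' Checks the invariants every downstream stage relies on: positive
#' populations, urban population not exceeding total, non-negative counts and
#' covariates, and death counts present for all analysis years.
#'
#' @param frame A `study_frame`.
#' @return Invisibly, a list describing the checks performed (used for the
#'   JSON validation report written by [run_pipeline()]).
#' @export
validate_study_frame <- function(frame) {
  years <- attr(frame, "years")
  fail <- function(unit, what)
    stop("unit '", unit, "': ", what, call. = FALSE)
  for (i in seq_len(nrow(frame))) {
    u <- frame$unit_id[i]
    if (!(frame$population[i] > 0)) fail(u, "population must be > 0")
    if (frame$urban_population[i] > frame$population[i])
      fail(u, "urban_population exceeds population")
    if (frame$urban_population[i] < 0) fail(u, "urban_population negative")
    if (!(frame$built_up_area_km2[i] > 0)) fail(u, "built_up_area_km2 must be > 0")
    if (frame$nh_length_km[i] < 0) fail(u, "nh_length_km negative")
    if (frame$diesel_kt[i] < 0) fail(u, "diesel_kt negative")
    for (y in years) {
      d <- frame[[paste0("deaths_", y)]][i]
      if (is.na(d) || d < 0) fail(u, paste0("deaths_", y, " missing or negative"))
    }
  }
  invisible(list(n_units = nrow(frame), years = years, ok = TRUE))
}

#' Drop island units from a study frame
#'
#' The two island union territories are excluded from the analysis (their
#' road systems are not connected to the mainland network and they contribute
#' a vanishing share of population). Removal preserves the order of the
#' remaining units and is idempotent.
#'
#' @param frame A `study_frame` with the `is_island` flag set.
#' @return The filtered `study_frame`.
#' @export
filter_units <- function(frame) {
  keep <- !frame$is_island
  out <- frame[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_study_frame(out, attr(frame, "years"))
}

#' Average annual road fatalities for one unit
#'
#' Arithmetic mean of the yearly road-death counts over the analysis years,
#' used in place of a single year for stable estimates. When railway-crossing
#' death counts are supplied they are subtracted year-wise before averaging,
#' so the result is the on-road burden only.
#'
#' @param unit One-row slice of a `study_frame` (or a list with the same
#'   fields).
#' @param years Analysis years; defaults to the frame's years attribute or
#'   2010:2012.
#' @param subtract_rail Subtract `rail_deaths_<year>` when present
#'   (default TRUE).
#' @return Mean deaths per year (real).
#' @export
average_annual_fatalities <- function(unit, years = NULL, subtract_rail = TRUE) {
  years <- years %||% attr(unit, "years") %||% 2010:2012
  vals <- vapply(years, function(y) {
    col <- paste0("deaths_", y)
    if (is.null(unit[[col]]) || is.na(unit[[col]]))
      stop("missing death count for year ", y)
    d <- unit[[col]]
    rcol <- paste0("rail_deaths_", y)
    if (subtract_rail && !is.null(unit[[rcol]]) && !is.na(unit[[rcol]]))
      d <- d - unit[[rcol]]
    as.numeric(d)
  }, numeric(1))
  mean(vals)
}

#' Fatality rate per 100,000 persons per year
#'
#' @inheritParams average_annual_fatalities
#' @return Average annual deaths per 100,000 population.
#' @export
fatality_rate <- function(unit, years = NULL, subtract_rail = TRUE) {
  pop <- unit[["population"]]
  if (is.null(pop) || is.na(pop) || pop <= 0) stop("population must be > 0")
  average_annual_fatalities(unit, years, subtract_rail) / pop * 1e5
}

#' Per-unit fatality summaries for a whole frame
#'
#' @param frame A `study_frame`.
#' @inheritParams average_annual_fatalities
#' @return data.frame with `unit_id`, `mean_deaths`, `rate_per_100k`.
#' @export
fatality_summary <- function(frame, subtract_rail = TRUE) {
  years <- attr(frame, "years")
  md <- vapply(seq_len(nrow(frame)), function(i)
    average_annual_fatalities(frame[i, , drop = FALSE], years, subtract_rail),
    numeric(1))
  data.frame(unit_id = frame$unit_id,
             mean_deaths = md,
             rate_per_100k = md / frame$population * 1e5,
             stringsAsFactors = FALSE)
}
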