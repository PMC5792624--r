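#' Default mode-shift risk exponents
#'
#' The multiplicative scenario model treats expected fatalities as
#' f = walk^e_walk * cycle^e_cycle * IPT^e_IPT * bus^e_bus * 2W^e_2W *
#' car^e_car (intercept and control covariates drop out of the risk ratio).
#' Defaults are the rounded final-model coefficient means
#' (walk -0.36, cycle -0.2, IPT -0.23, bus 0.07, 2W 0.39, car 0.26);
#' `precision = "full"` substitutes the unrounded means
#' (-0.355, -0.200, -0.234, 0.066, 0.390, 0.263).
#'
#' @param precision `"rounded"` (default) or `"full"`.
#' @return Named numeric vector over the six on-road modes.
#' @export
scenario_exponents <- function(precision = c("rounded", "full")) {
  precision <- match.arg(precision)
  if (precision == "rounded")
    c(walk = -0.36, cycle = -0.2, IPT = -0.23, bus = 0.07,
      `2W` = 0.39, car = 0.26)
  else
    c(walk = -0.355, cycle = -0.200, IPT = -0.234, bus = 0.066,
      `2W` = 0.390, car = 0.263)
}

#' Define a stepwise mode-shift scenario
#'
#' At each step a fixed number of percentage points of mode share moves from
#' `from_mode` to `to_mode`; all other shares (and the total) are unchanged,
#' so total travel distance is conserved.
#'
#' @param from_mode,to_mode Distinct on-road mode names.
#' @param step_pp Percentage points shifted per step (default 0.5).
#' @param n_steps Number of curve points including the baseline (default 10).
#' @param exponents Named risk exponents covering the six on-road modes.
#' @return List of class `scenario_def`.
#' @export
scenario_def <- function(from_mode, to_mode, step_pp = 0.5, n_steps = 10,
                         exponents = scenario_exponents()) {
  if (from_mode == to_mode) stop("from_mode and to_mode must differ")
  if (!(step_pp > 0)) stop("step_pp must be > 0")
  missing <- setdiff(rr_model_modes(), names(exponents))
  if (length(missing))
    stop("exponents missing for mode(s): ", paste(missing, collapse = ", "))
  structure(list(from_mode = from_mode, to_mode = to_mode,
                 step_pp = step_pp, n_steps = as.integer(n_steps),
                 exponents = exponents), class = "scenario_def")
}

#' Shift mode shares by a number of scenario steps
#'
#' @param shares Named share vector (fractions).
#' @param def A [scenario_def()].
#' @param step_index Non-negative integer; 0 is the baseline.
#' @return Shifted share vector, or `NULL` with a warning-free truncation
#'   signal (attribute-free): the function returns `NULL` when the shift
#'   would drive the source share below zero.
#' @export
shift_shares <- function(shares, def, step_index) {
  if (step_index < 0) stop("step_index must be >= 0")
  move <- step_index * def$step_pp / 100
  new_from <- shares[[def$from_mode]] - move
  if (new_from < 0) return(NULL)  # truncation: step not evaluable
  shares[[def$from_mode]] <- new_from
  shares[[def$to_mode]] <- shares[[def$to_mode]] + move
  shares
}

#' Relative risk of a shifted share vector against a baseline
#'
#' RR = prod over modes of (share_m / baseline_m)^exponent_m. Because the
#' model is multiplicative and total distance is conserved, using shares or
#' absolute distances gives the same ratio (the constant total cancels).
#'
#' @param shares,baseline Named vectors covering every mode with a nonzero
#'   exponent; positive wherever the exponent is nonzero.
#' @param exponents Named risk exponents.
#' @return Scalar RR; exactly 1 when `shares` equals `baseline`.
#' @export
relative_risk <- function(shares, baseline,
                          exponents = scenario_exponents()) {
  modes <- names(exponents)[exponents != 0]
  s <- unlist(shares)[modes]
  b <- unlist(baseline)[modes]
  if (anyNA(s) || anyNA(b))
    stop("shares missing for mode(s) with nonzero exponent")
  if (any(b <= 0)) stop("baseline share must be > 0 where exponent != 0")
  if (any(s < 0)) stop("negative share")
  if (any(s == 0 & exponents[modes] < 0))
    stop("zero share with negative exponent: risk ratio undefined")
  exp(sum(exponents[modes] * (log(s) - log(b))))
}

#' Run a mode-shift scenario from a baseline share vector
#'
#' Evaluates steps 0..n_steps-1, stopping early (with `truncated = TRUE`)
#' as soon as a step would drive the source-mode share below zero.
#'
#' @param baseline Named share vector (the six on-road modes, or all seven;
#'   must include the scenario's modes with positive values).
#' @param def A [scenario_def()].
#' @return Object of class `rr_curve`: list with `baseline`, `steps`
#'   (data.frame with `step`, `rr` and the shifted shares), `truncated`.
#' @export
run_scenario <- function(baseline, def) {
  baseline <- unlist(baseline)
  rows <- list()
  truncated <- FALSE
  for (i in seq_len(def$n_steps) - 1L) {
    sh <- shift_shares(baseline, def, i)
    if (is.null(sh) ||
        (sh[[def$from_mode]] == 0 && def$exponents[[def$from_mode]] < 0)) {
      # source share exhausted (or RR undefined at zero): curve ends here
      truncated <- TRUE
      break
    }
    rr <- if (i == 0) 1 else relative_risk(sh, baseline, def$exponents)
    rows[[length(rows) + 1L]] <-
      data.frame(step = i, rr = rr, t(sh), check.names = FALSE)
  }
  structure(list(baseline = baseline, def = def,
                 steps = do.call(rbind, rows), truncated = truncated),
            class = "rr_curve")
}

#' @export
print.rr_curve <- function(x, ...) {
  cat("Mode-shift scenario ", x$def$from_mode, " -> ", x$def$to_mode,
      " (", x$def$step_pp, " pp/step, ", nrow(x$steps), " points",
      if (x$truncated) ", truncated", ")\n", sep = "")
  print(round(stats::setNames(x$steps$rr, x$steps$step), 4))
  invisible(x)
}

#' @export
plot.rr_curve <- function(x, ...) {
  graphics::plot(x$steps$step, x$steps$rr, type = "b", pch = 19,
                 xlab = "shift step", ylab = "relative risk", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Detect an interior turning point of a relative-risk curve
#'
#' Returns the 0-based step index of the first strict interior local
#' extremum, or `NA` when the curve is monotone. `direction = "min"` finds
#' a local minimum (a U); `direction = "max"` finds a local maximum — the
#' critical point of a rise-then-fall fatality curve beyond which further
#' mode shift improves safety.
#'
#' @param curve An `rr_curve` or a numeric RR vector.
#' @param direction `"min"` (default) or `"max"`.
#' @return Integer index (0-based, matching `steps$step`) or `NA`.
#' @export
detect_turning_point <- function(curve, direction = c("min", "max")) {
  direction <- match.arg(direction)
  rr <- if (inherits(curve, "rr_curve")) curve$steps$rr else as.numeric(curve)
  if (length(rr) < 3) stop("curve must have at least 3 points")
  if (direction == "max") rr <- -rr
  for (i in 2:(length(rr) - 1)) {
    if (rr[i] < rr[i - 1] && rr[i] < rr[i + 1]) return(i - 1L)
  }
  NA_integer_
}

#' Run the three canonical scenarios for a set of baselines
#'
#' Scenario A shifts 2W to car, B shifts walk to 2W, C shifts cycle to 2W.
#'
#' @param baselines data.frame with a `cluster` (or `unit_id`) column and
#'   `share_<mode>` columns, e.g. the output of [cluster_profile()].
#' @param step_pp,n_steps,exponents Passed to [scenario_def()].
#' @return data.frame: one row per baseline x scenario x step with shares,
#'   RR and the truncation flag.
#' @export
run_scenarios <- function(baselines, step_pp = 0.5, n_steps = 10,
                          exponents = scenario_exponents()) {
  defs <- list(A = scenario_def("2W", "car", step_pp, n_steps, exponents),
               B = scenario_def("walk", "2W", step_pp, n_steps, exponents),
               C = scenario_def("cycle", "2W", step_pp, n_steps, exponents))
  id_col <- if ("cluster" %in% names(baselines)) "cluster" else "unit_id"
  out <- list()
  for (r in seq_len(nrow(baselines))) {
    shares <- vapply(rr_model_modes(), function(md)
      baselines[[paste0("share_", md)]][r], numeric(1))
    for (sc in names(defs)) {
      cur <- run_scenario(shares, defs[[sc]])
      df <- cur$steps
      df$scenario <- sc
      df[[id_col]] <- baselines[[id_col]][r]
      df$truncated <- cur$truncated
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}
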