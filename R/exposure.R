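#' Representative one-way distance per census bin
#'
#' The census reports commute distance in seven bins. Each bin is collapsed
#' to a representative one-way distance: the closed bins to their midpoints,
#' the open ended `>50` bin to a configurable value (default 60 km). Per-bin
#' overrides allow substituting externally estimated within-bin averages.
#'
#' @param overrides Optional named numeric vector/list of per-bin distances;
#'   if given it must cover all seven bins with positive values.
#' @param open_bin_km Representative distance for the `>50` bin when no
#'   overrides are given.
#' @return Named numeric vector, one entry per bin label.
#' @export
bin_representative_distances <- function(overrides = NULL, open_bin_km = 60) {
  bins <- rr_bins()
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    missing <- setdiff(bins, names(overrides))
    if (length(missing))
      stop("override missing bin(s): ", paste(missing, collapse = ", "))
    reps <- as.numeric(overrides[bins])
    if (any(!is.finite(reps)) || any(reps <= 0))
      stop("bin distances must be positive and finite")
    return(stats::setNames(reps, bins))
  }
  if (!is.finite(open_bin_km) || open_bin_km <= 0)
    stop("open_bin_km must be positive")
  stats::setNames(c(0.5, 3.5, 8, 15.5, 25.5, 40.5, open_bin_km), bins)
}

#' Load binned commute counts from CSV
#'
#' Long format: one row per unit x mode x bin with a worker count. Water
#' transport and "any other" categories are expected to be absent (they are
#' excluded at ingest).
#'
#' @param path CSV with columns `unit_id`, `mode`, `bin_label`, `workers`.
#' @return data.frame validated against mode/bin labels and the structural
#'   walk/cycle distance caps.
#' @export
load_commute_bins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("unit_id", "mode", "bin_label", "workers")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  validate_commute_bins(df)
  df
}

validate_commute_bins <- function(df) {
  bad_mode <- setdiff(unique(df$mode), rr_modes())
  if (length(bad_mode))
    stop("unknown mode(s): ", paste(bad_mode, collapse = ", "))
  bad_bin <- setdiff(unique(df$bin_label), rr_bins())
  if (length(bad_bin))
    stop("unknown bin label(s): ", paste(bad_bin, collapse = ", "))
  if (any(!is.finite(df$workers)) || any(df$workers < 0))
    stop("worker counts must be finite and >= 0")
  cap <- rr_mode_bin_cap()
  bin_idx <- match(df$bin_label, rr_bins())
  over <- df$workers > 0 & bin_idx > cap[df$mode]
  if (any(over)) {
    r <- which(over)[1]
    stop("structural zero violated: mode '", df$mode[r], "' has ",
         df$workers[r], " workers in bin '", df$bin_label[r],
         "' (unit ", df$unit_id[r], ")")
  }
  invisible(TRUE)
}

# long data.frame -> mode x bin count matrix for one unit
bins_matrix <- function(df_unit) {
  m <- matrix(0, nrow = 7, ncol = 7, dimnames = list(rr_modes(), rr_bins()))
  idx <- cbind(match(df_unit$mode, rr_modes()), match(df_unit$bin_label, rr_bins()))
  m[idx] <- m[idx] + df_unit$workers
  m
}

#' Total one-way commute distance per mode
#'
#' For each mode, sums worker count times the representative bin distance
#' over bins: the total daily one-way commute kilometres by that mode.
#'
#' @param counts mode x bin matrix of worker counts (rows named by
#'   [rr_modes()], columns by [rr_bins()]), or a long data.frame for a single
#'   unit as read by [load_commute_bins()].
#' @param reps Named per-bin representative distances from
#'   [bin_representative_distances()].
#' @return Named numeric vector, km per mode.
#' @export
total_mode_distance <- function(counts, reps = bin_representative_distances()) {
  if (is.data.frame(counts)) counts <- bins_matrix(counts)
  stopifnot(identical(rownames(counts), rr_modes()),
            identical(colnames(counts), rr_bins()))
  drop(counts %*% reps[rr_bins()])
}

#' Add public-transport access walking to the walk distance
#'
#' Commuters report their main mode only, so walking to and from public
#' transport stops is invisible in the raw counts. Every IPT, bus or train
#' commuter whose trip is longer than 1 km (i.e. in any bin beyond 0-1 km) is
#' assumed to add `walk_per_trip` km of walking (covering both ends of the
#' trip). Train's vehicular distance never enters the model, but its access
#' walking does: it is covered on the road.
#'
#' @param counts mode x bin matrix (or long data.frame) of worker counts.
#' @param distances Named per-mode distance vector from
#'   [total_mode_distance()].
#' @param walk_per_trip km of walking credited per qualifying PT commuter;
#'   0, 1 (default) and 1.5 form the sensitivity grid.
#' @return `distances` with the walk entry incremented; an attribute
#'   `pt_walk_km` records the added kilometres.
#' @export
add_pt_access_walk <- function(counts, distances, walk_per_trip = 1) {
  if (!is.finite(walk_per_trip) || walk_per_trip < 0)
    stop("walk_per_trip must be >= 0")
  if (is.data.frame(counts)) counts <- bins_matrix(counts)
  beyond_1km <- setdiff(rr_bins(), "0-1")
  n_pt <- sum(counts[rr_pt_modes(), beyond_1km])
  added <- walk_per_trip * n_pt
  distances["walk"] <- distances["walk"] + added
  attr(distances, "pt_walk_km") <- added
  distances
}

#' Mode shares of total commute distance
#'
#' Each mode's share is its commute distance divided by the total over the
#' included modes; shares sum to one. Shares put units with very different
#' travel volumes on a common scale.
#'
#' @param distances Named per-mode distance vector.
#' @param modes Modes to include (default all seven, including train).
#' @return Named numeric vector of shares summing to 1.
#' @export
mode_shares <- function(distances, modes = rr_modes()) {
  d <- distances[modes]
  if (anyNA(d)) stop("distances missing for mode(s): ",
                     paste(modes[is.na(d)], collapse = ", "))
  tot <- sum(d)
  if (tot <= 0) stop("all included mode distances are zero")
  d / tot
}

#' Build the exposure table for all units
#'
#' Runs the full exposure construction: bin distances, per-mode totals, the
#' PT access-walk augmentation, and mode shares.
#'
#' @param bins Long data.frame of commute bin counts
#'   (see [load_commute_bins()]).
#' @param reps Per-bin representative distances.
#' @param walk_per_trip PT access-walk km per qualifying commuter.
#' @return data.frame with one row per unit: `dist_<mode>` columns (km),
#'   `pt_walk_km`, and `share_<mode>` columns.
#' @export
build_exposure <- function(bins, reps = bin_representative_distances(),
                           walk_per_trip = 1) {
  validate_commute_bins(bins)
  units <- unique(bins$unit_id)
  rows <- lapply(units, function(u) {
    m <- bins_matrix(bins[bins$unit_id == u, , drop = FALSE])
    d <- total_mode_distance(m, reps)
    d <- add_pt_access_walk(m, d, walk_per_trip)
    s <- mode_shares(d)
    out <- data.frame(unit_id = u, stringsAsFactors = FALSE)
    for (md in rr_modes()) out[[paste0("dist_", md)]] <- unname(d[md])
    out$pt_walk_km <- attr(d, "pt_walk_km")
    for (md in rr_modes()) out[[paste0("share_", md)]] <- unname(s[md])
    out
  })
  do.call(rbind, rows)
}

#' Extract the unit-by-mode share matrix from an exposure table
#'
#' @param exposure Output of [build_exposure()].
#' @return Numeric matrix, units x modes, rows named by `unit_id`.
#' @export
share_matrix <- function(exposure) {
  cols <- paste0("share_", rr_modes())
  m <- as.matrix(exposure[, cols])
  dimnames(m) <- list(exposure$unit_id, rr_modes())
  m
}
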