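#' Travel modes and census distance bins
#'
#' The commute data distinguish seven main modes of travel to work and seven
#' one-way distance bins. Walking is only reported up to the 6-10 km bin and
#' cycling up to the 21-30 km bin; counts beyond those bins are structural
#' zeros. Train is a valid exposure mode (its access walking happens on the
#' road) but its vehicular distance never enters the fatality model.
#'
#' @format Character vectors of mode and bin labels.
#' @name modes
NULL

#' @rdname modes
#' @export
rr_modes <- function() c("walk", "cycle", "2W", "car", "IPT", "bus", "train")

#' @rdname modes
#' @export
rr_bins <- function() c("0-1", "2-5", "6-10", "11-20", "21-30", "31-50", ">50")

# on-road modes entering the regression model (train vehicular distance excluded)
rr_model_modes <- function() c("bus", "IPT", "car", "walk", "cycle", "2W")

# public-transport modes whose trips generate access/egress walking
rr_pt_modes <- function() c("IPT", "bus", "train")

# last bin index with admissible counts per mode (structural zeros beyond)
rr_mode_bin_cap <- function() {
  cap <- stats::setNames(rep(7L, 7L), rr_modes())
  cap["walk"] <- 3L   # up to 6-10 km
  cap["cycle"] <- 5L  # up to 21-30 km
  cap
}

`%||%` <- function(a, b) if (is.null(a)) b else a
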