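#' Initial rate of dye uptake
#'
#' Reduces a fluorescence time course to the initial uptake rate: the
#' ordinary least-squares slope of fluorescence against time over the first
#' `window_points` samples, after subtracting the t = 0 baseline. Initial
#' rates, rather than total counts at an endpoint, are used because uptake
#' activity declines late in a recording and endpoint counts conflate
#' activation with that decline.
#'
#' @param series A data frame with columns `time_s` (strictly increasing,
#'   starting at agonist addition) and `fluorescence_au`.
#' @param window_points Number of leading samples in the fit window
#'   (default 5, i.e. 0-4 min at 1-min sampling).
#' @return Slope in arbitrary units per second.
#' @export
initial_rate <- function(series, window_points = 5L) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "fluorescence_au") %in% names(series)))
  t <- series$time_s; f <- series$fluorescence_au
  if (any(!is.finite(t)) || any(!is.finite(f)))
    stop("times and fluorescence must be finite", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  if (length(t) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (window_points < 2L || window_points > length(t))
    stop("`window_points` must be in [2, length(series)]", call. = FALSE)
  idx <- seq_len(window_points)
  tw <- t[idx]; fw <- f[idx] - f[1L]
  if (diff(range(tw)) == 0) stop("zero time span in window", call. = FALSE)
  unname(stats::coef(stats::lm(fw ~ tw))[2L])
}

#' Drop samples recorded after uptake starts to decline
#'
#' Uptake activity begins to fall roughly 10 min after agonist application;
#' samples beyond the cutoff (default 600 s) are removed before rate
#' extraction so the late decline cannot bias the slope.
#'
#' @param series Data frame with a `time_s` column.
#' @param cutoff_s Retain samples with `time_s <= cutoff_s`.
#' @return The truncated series.
#' @export
truncate_decline <- function(series, cutoff_s = 600) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series))
  series[series$time_s <= cutoff_s, , drop = FALSE]
}

#' Normalize raw uptake rates to the plate's control condition
#'
#' Divides every raw rate by the mean control rate of its plate, where the
#' control condition is maximal agonist with no antagonist; the control
#' mean maps to a normalized response of 1. Normalization is per plate so
#' day-to-day gain differences cancel.
#'
#' @param rates Data frame with columns `agonist_conc_M`,
#'   `antagonist_conc_M`, `rate_au_per_s`, `replicate`, and optionally
#'   `plate_id` (a single implicit plate otherwise) and `antagonist_id`.
#' @return The input with a `response` column of normalized rates.
#' @export
normalize_rates <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("agonist_conc_M", "antagonist_conc_M",
                  "rate_au_per_s") %in% names(rates)))
  if (!"plate_id" %in% names(rates)) rates$plate_id <- "plate1"
  out <- rates
  out$response <- NA_real_
  for (pl in unique(rates$plate_id)) {
    sel <- rates$plate_id == pl
    amax <- max(rates$agonist_conc_M[sel])
    ctrl <- sel & rates$agonist_conc_M == amax & rates$antagonist_conc_M == 0
    if (!any(ctrl))
      stop("plate ", pl, " has no control condition ",
           "(maximal agonist, zero antagonist)", call. = FALSE)
    out$response[sel] <- rates$rate_au_per_s[sel] /
      mean(rates$rate_au_per_s[ctrl])
  }
  out
}

#' Reduce a table of uptake time courses to a dose-response table
#'
#' Applies [truncate_decline()], extracts [initial_rate()] per recording,
#' and normalizes per plate with [normalize_rates()]. One row per
#' (condition, replicate) recording comes out.
#'
#' @param timeseries Long data frame in the `timeseries.csv` schema:
#'   `time_s`, `fluorescence_au`, `agonist_conc_M`, `antagonist_id`,
#'   `antagonist_conc_M`, `replicate`, `plate_id`.
#' @param window_points Fit window passed to [initial_rate()].
#' @param cutoff_s Decline cutoff passed to [truncate_decline()].
#' @return Data frame with one row per recording: condition columns,
#'   `rate_au_per_s`, and normalized `response`; the window and cutoff used
#'   are attached as attributes `window_points` and `cutoff_s`.
#' @export
rates_from_timeseries <- function(timeseries, window_points = 5L,
                                  cutoff_s = 600) {
  stopifnot(is.data.frame(timeseries))
  if (!"plate_id" %in% names(timeseries)) timeseries$plate_id <- "plate1"
  key <- interaction(timeseries$agonist_conc_M, timeseries$antagonist_id,
                     timeseries$antagonist_conc_M, timeseries$replicate,
                     timeseries$plate_id, drop = TRUE)
  pieces <- lapply(split(timeseries, key), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    r <- initial_rate(truncate_decline(d, cutoff_s), window_points)
    data.frame(agonist_conc_M = d$agonist_conc_M[1L],
               antagonist_id = d$antagonist_id[1L],
               antagonist_conc_M = d$antagonist_conc_M[1L],
               replicate = d$replicate[1L],
               plate_id = d$plate_id[1L],
               rate_au_per_s = r)
  })
  out <- normalize_rates(do.call(rbind, c(pieces, make.row.names = FALSE)))
  attr(out, "window_points") <- window_points
  attr(out, "cutoff_s") <- cutoff_s
  out
}
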