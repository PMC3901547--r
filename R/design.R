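#' Temporal sampling design
#'
#' Describes when diploid samples were collected, how many individuals each
#' contains, how many microsatellite loci were typed, and when IRS spray
#' rounds took place.  Optionally carries a monthly rainfall series used by
#' the rainfall-correlation scenarios.
#'
#' @param dates ordered vector of collection `Date`s (one per temporal
#'   sample); the last one is the conventional clock reference.
#' @param sizes positive integer number of diploid individuals per sample.
#' @param n_loci number of microsatellite loci (>= 1).
#' @param spray_dates `Date`s of IRS rounds: the round preceding the study
#'   plus the in-study rounds.
#' @param rainfall optional rainfall series from [rainfall_series()].
#' @return An object of class `sampling_design`.
#' @seealso [default_design()] for the Mongola study layout.
#' @export
sampling_design <- function(dates, sizes, n_loci = 13,
                            spray_dates = NULL, rainfall = NULL) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(sizes), !is.unsorted(dates),
            all(sizes > 0), n_loci >= 1)
  if (!is.null(spray_dates)) spray_dates <- sort(as.Date(spray_dates))
  if (!is.null(rainfall)) stopifnot(inherits(rainfall, "rainfall_series"))
  structure(list(dates = dates, sizes = as.integer(sizes),
                 n_loci = as.integer(n_loci),
                 spray_dates = spray_dates, rainfall = rainfall),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("<sampling_design> %d samples, %d individuals, %d loci\n",
              length(x$dates), sum(x$sizes), x$n_loci))
  cat("  samples:", paste0(format(x$dates), " (n=", x$sizes, ")",
                           collapse = ", "), "\n")
  if (!is.null(x$spray_dates))
    cat("  spray rounds:", paste(format(x$spray_dates), collapse = ", "), "\n")
  invisible(x)
}

#' The Mongola (Bioko Island) study design
#'
#' Six temporal samples of 125/142/137/147/146/95 diploid individuals typed
#' at 13 microsatellite loci, collected March 2009 - April 2010, with one
#' spray round preceding the study (October 2008) and two in-study rounds
#' (June and December 2009).  Multi-day collection and spray windows are
#' represented by their midpoint dates.
#'
#' @param rainfall rainfall series attached to the design; defaults to the
#'   synthetic Bioko series ([rainfall_series_synthetic()]).
#' @return A [sampling_design()].
#' @export
default_design <- function(rainfall = rainfall_series_synthetic()) {
  sampling_design(
    dates = as.Date(c("2009-03-25", "2009-05-18", "2009-07-07",
                      "2009-08-31", "2009-11-10", "2010-04-13")),
    sizes = c(125L, 142L, 137L, 147L, 146L, 95L),
    n_loci = 13L,
    spray_dates = as.Date(c("2008-10-01", "2009-06-14", "2009-12-18")),
    rainfall = rainfall
  )
}

#' Monthly rainfall series
#'
#' @param months `Date` vector of month starts.
#' @param mm non-negative precipitation totals (mm) per month.
#' @return An object of class `rainfall_series`.
#' @export
rainfall_series <- function(months, mm) {
  months <- as.Date(months)
  stopifnot(length(months) == length(mm), all(mm >= 0), !is.unsorted(months))
  structure(list(months = months, mm = as.numeric(mm)),
            class = "rainfall_series")
}

#' Synthetic Bioko Island monthly rainfall, March 2009 - April 2010
#'
#' The study-site rain gauge record is not published month by month; only
#' the March-November 2009 total (1919 mm), the wet-season span
#' (April-October) and the extraordinary 177 mm deluge of 22 June 2009 are
#' reported.  This synthetic series is constrained to reproduce those
#' features: it sums to 1919 mm over March-November 2009, peaks in June, and
#' is nearly dry December-February.  It is used only to define the rank
#' ordering of interval rainfall for the rainfall-correlation scenarios and
#' is clearly a stand-in, not an observation.
#'
#' @return A [rainfall_series()] covering 2009-03 through 2010-04.
#' @export
rainfall_series_synthetic <- function() {
  rainfall_series(
    months = seq(as.Date("2009-03-01"), as.Date("2010-04-01"), by = "month"),
    mm = c(120, 200, 230, 320, 260, 250, 230, 180, 129,  # Mar-Nov 2009: 1919
           35, 10, 15, 120, 200)                         # Dec 2009 - Apr 2010
  )
}

#' Mean rainfall per sampling interval
#'
#' Day-weighted mean of the monthly series over each interval between
#' consecutive sampling dates.  Used to build the rank-order constraints of
#' the rainfall-correlation scenarios.
#'
#' @param design a [sampling_design()] with a rainfall series attached.
#' @return Numeric vector of length `length(design$dates) - 1`.
#' @export
interval_rainfall_means <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  rf <- design$rainfall
  if (is.null(rf)) stop("design has no rainfall series")
  month_start <- rf$months
  month_end <- seq(min(month_start), by = "month",
                   length.out = length(month_start) + 1)[-1]
  ivl_start <- design$dates[-length(design$dates)]
  ivl_end <- design$dates[-1]
  if (min(ivl_start) < min(month_start) || max(ivl_end) > max(month_end))
    stop("rainfall series does not cover every month of the sampling design")
  vapply(seq_along(ivl_start), function(i) {
    ov_days <- pmax(0, as.numeric(
      pmin(month_end, ivl_end[i]) - pmax(month_start, ivl_start[i])))
    sum(ov_days * rf$mm) / sum(ov_days)
  }, numeric(1))
}
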