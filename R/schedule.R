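#' Light/dark schedule
#'
#' Describes the vivarium photoperiod. All phase attribution in the package is
#' anchored at lights-on: the analysis "day" runs from one lights-on to the
#' next, so that "hour 0 post lights-on" is the first light hour, matching the
#' convention of hourly home-cage activity plots. Phase intervals are half-open
#' `[lights_on, lights_off)`: a sample stamped exactly at lights-off belongs to
#' the dark phase.
#'
#' @param lights_on,lights_off Times of day as `"HH:MM"` strings (defaults
#'   07:00 and 19:00, i.e. a 12:12 cycle).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule()
#' @export
light_schedule <- function(lights_on = "07:00", lights_off = "19:00") {
  parse_tod <- function(x) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    if (length(p) < 2 || anyNA(p)) stop("times must be 'HH:MM'", call. = FALSE)
    p[1] * 3600 + p[2] * 60
  }
  on <- parse_tod(lights_on)
  off <- parse_tod(lights_off)
  if (on == off) stop("lights_on and lights_off must differ", call. = FALSE)
  structure(
    list(
      lights_on = lights_on, lights_off = lights_off,
      on_sec = on, off_sec = off,
      light_hours = ((off - on) %% 86400) / 3600
    ),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> lights on %s-%s (%g h light / %g h dark)\n",
    x$lights_on, x$lights_off, x$light_hours, 24 - x$light_hours
  ))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#'
#' @param lambda Capacitance-difference threshold for the graded activity
#'   metric (activation density). The vendor value is unpublished; the default
#'   is four times `lambda_immobility`, and only the ordering of the two
#'   thresholds matters for the pipeline's monotonicity guarantees.
#' @param lambda_immobility Threshold on the difference of two consecutive 1-s
#'   average capacitance windows below which an electrode is considered not
#'   activated; the default 1.25 is the lowest usable value and defines the
#'   per-second immobility series (both co-housed animals immobile).
#' @param samp_en_m Sample-entropy embedding dimension (default 2).
#' @param samp_en_r Sample-entropy tolerance as a fraction of the SD of the
#'   filtered phase segment (default 0.2).
#' @param band_low_period,band_high_period Butterworth passband bounds for the
#'   minute-activity series, expressed as periods in minutes (default 2 and
#'   120 min). A `band_low_period` at or below twice the sampling interval
#'   cannot be realized by a discrete filter and degrades gracefully to a
#'   high-pass at `1/band_high_period` (trend/DC removal only).
#' @param filter_order Butterworth order (default 2).
#' @param smooth_window Centred moving-average window (minutes, odd) for the
#'   smoothed activity index (default 3).
#' @param fs Capacitance sampling rate in Hz (default 4; configurable because
#'   activation densities depend only weakly on it).
#' @param bout_min Minimum rest-bout length in seconds (default 40 s, the
#'   established behavioural sleep proxy for mice).
#' @param bout_bins Interior bout-duration bin edges in minutes (default
#'   `c(5, 15)`, giving bins <5, 5-15, >15 min).
#' @param long_bout_threshold Threshold in minutes for the long-bout rest
#'   fraction (default 30).
#' @param seed Optional integer seed recorded with results.
#' @return An object of class `analysis_config`.
#' @examples
#' analysis_config()
#' @export
analysis_config <- function(lambda = 5,
                            lambda_immobility = 1.25,
                            samp_en_m = 2L,
                            samp_en_r = 0.2,
                            band_low_period = 2,
                            band_high_period = 120,
                            filter_order = 2L,
                            smooth_window = 3L,
                            fs = 4,
                            bout_min = 40,
                            bout_bins = c(5, 15),
                            long_bout_threshold = 30,
                            seed = NULL) {
  stopifnot(
    lambda > 0, lambda_immobility > 0,
    samp_en_m >= 1, samp_en_r > 0,
    band_low_period > 0, band_high_period > band_low_period,
    filter_order >= 1, smooth_window >= 1, fs > 0,
    bout_min > 0, long_bout_threshold > 0
  )
  if (is.unsorted(bout_bins, strictly = TRUE)) {
    stop("bout_bins edges must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      lambda = lambda, lambda_immobility = lambda_immobility,
      samp_en_m = as.integer(samp_en_m), samp_en_r = samp_en_r,
      band_low_period = band_low_period, band_high_period = band_high_period,
      filter_order = as.integer(filter_order),
      smooth_window = as.integer(smooth_window), fs = fs,
      bout_min = bout_min, bout_bins = bout_bins,
      long_bout_threshold = long_bout_threshold, seed = seed
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  lambda = %g, lambda_immobility = %g, fs = %g Hz\n",
              x$lambda, x$lambda_immobility, x$fs))
  cat(sprintf("  sample entropy: m = %d, r = %g * SD\n", x$samp_en_m, x$samp_en_r))
  cat(sprintf("  band-pass periods: %g-%g min, order %d\n",
              x$band_low_period, x$band_high_period, x$filter_order))
  cat(sprintf("  rest bouts: >= %g s, bins at %s min, long-bout > %g min\n",
              x$bout_min, paste(x$bout_bins, collapse = ", "),
              x$long_bout_threshold))
  invisible(x)
}
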