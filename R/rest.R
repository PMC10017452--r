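#' Percentage of zero-activity time per hour post lights-on
#'
#' For every cage and lights-on-anchored day, the percentage of immobile
#' (zero-activity) seconds in each of the 24 hours, hour 1 being the first
#' hour after lights-on. Masked seconds are removed from the denominator;
#' an hour with no unmasked seconds is `NA`.
#'
#' @param immobility Tibble `timestamp, cage_id, immobile` (1-s resolution).
#' @param schedule A [light_schedule()].
#' @return Tibble `cage_id, day, hour (1-24), phase, pct_zero, n_seconds`.
#' @export
percent_zero_per_hour <- function(immobility, schedule = light_schedule()) {
  light_hours <- schedule$light_hours
  immobility |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      ts <- as.numeric(d$timestamp)
      # whole hours since the epoch lights-on: encodes (day, hour) in one key
      slot <- (ts - schedule$on_sec) %/% 3600
      v <- d$immobile
      ok <- !is.na(v)
      s0 <- min(slot)
      idx <- as.integer(slot - s0 + 1)
      nb <- max(idx)
      n_sec <- tabulate(idx[ok], nbins = nb)
      n_imm <- tabulate(idx[ok & v == 1L], nbins = nb)
      present <- tabulate(idx, nbins = nb) > 0L
      uslot <- (s0 + which(present) - 1)
      n_sec <- n_sec[present]; n_imm <- n_imm[present]
      hr <- as.integer(uslot %% 24)
      tibble::tibble(
        day = as.Date(uslot %/% 24, origin = "1970-01-01"),
        hour = hr + 1L,
        phase = structure(2L - (hr < light_hours), levels = c("light", "dark"),
                          class = "factor"),
        pct_zero = ifelse(n_sec > 0, 100 * n_imm / n_sec, NA_real_),
        n_seconds = n_sec
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("cage_id", "day", "hour", "phase", "pct_zero", "n_seconds") |>
    dplyr::arrange(.data$cage_id, .data$day, .data$hour)
}

#' Least active consecutive hour of a day
#'
#' Finds, independently for every cage and 24-h day, the 60 consecutive
#' minutes with the lowest mean activity among all 1381 start offsets (the
#' window does not wrap across the lights-on day boundary). The least active
#' hour is a proxy for the most consolidated rest period of the day; in
#' healthy nocturnal mice it falls almost always in the light phase, so its
#' occurrence in the dark phase is a daytime-sleepiness-like signal. Masked
#' minutes are excluded from the window mean; windows with more than
#' `max_masked` masked minutes are skipped. Ties take the earliest start.
#'
#' @param activity Tibble `timestamp, cage_id, activity` (1-min resolution).
#' @param schedule A [light_schedule()].
#' @param max_masked Maximum masked minutes tolerated per window (default 10).
#' @return Tibble `cage_id, day, start_minute (0-1380, post lights-on),
#'   mean_activity, phase` (phase of the window start). Days with no valid
#'   window are dropped.
#' @export
least_active_hour <- function(activity, schedule = light_schedule(),
                              max_masked = 10) {
  light_min <- schedule$light_hours * 60
  assign_phases(activity, schedule) |>
    dplyr::mutate(
      offset = as.integer(((as.numeric(.data$timestamp) - schedule$on_sec) %% 86400) %/% 60)
    ) |>
    dplyr::group_by(.data$cage_id, .data$day) |>
    dplyr::group_modify(function(d, key) {
      x <- rep(NA_real_, 1440)
      x[d$offset + 1L] <- d$activity
      w <- lah_search(x, max_masked)
      if (is.null(w)) return(tibble::tibble())
      tibble::tibble(start_minute = w$start, mean_activity = w$mean)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      phase = factor(ifelse(.data$start_minute < light_min, "light", "dark"),
                     levels = c("light", "dark"))
    ) |>
    dplyr::arrange(.data$cage_id, .data$day)
}

# exhaustive scan of all 1381 non-wrapping 60-min windows
lah_search <- function(x, max_masked) {
  n <- length(x)
  if (n < 60) return(NULL)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  starts <- 0:(n - 60)
  s <- cs[starts + 61L] - cs[starts + 1L]
  k <- cn[starts + 61L] - cn[starts + 1L]
  valid <- (60L - k) <= max_masked & k > 0
  if (!any(valid)) return(NULL)
  mu <- ifelse(valid, s / k, Inf)
  i <- which.min(mu) # earliest index on ties
  list(start = starts[i], mean = mu[i])
}

#' Histogram of least-active-hour start times
#'
#' Bins least-active-hour start offsets (minutes post lights-on) into
#' fixed-width bins, respecting any dplyr grouping already on `lah` (e.g. by
#' sex and genotype). Use [lah_dark_fraction()] for the share of days whose
#' least active hour starts in the dark phase.
#'
#' @param lah Output of [least_active_hour()], optionally grouped.
#' @param bin_width Bin width in minutes (default 60).
#' @return Tibble with grouping columns, `bin_start_minute`, `n`, `prop`.
#' @export
least_active_hour_histogram <- function(lah, bin_width = 60) {
  gv <- dplyr::group_vars(lah)
  lah |>
    dplyr::mutate(bin_start_minute = (.data$start_minute %/% bin_width) * bin_width) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gv, "bin_start_minute")))) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' @rdname least_active_hour_histogram
#' @export
lah_dark_fraction <- function(lah) {
  lah |>
    dplyr::summarise(
      n = dplyr::n(),
      dark_fraction = mean(.data$phase == "dark"),
      .groups = "drop"
    )
}

#' Detect rest bouts
#'
#' A rest bout is a maximal run of consecutive immobile seconds lasting at
#' least `bout_min` seconds (default 40 s, the established behavioural proxy
#' for sleep in mice). Masked seconds and gaps in the 1-s grid terminate
#' runs, so a sensor gap is never bridged into a bout. Each bout is
#' attributed to the phase and day of its onset second.
#'
#' @param immobility Tibble `timestamp, cage_id, immobile` (1-s resolution).
#' @param bout_min Minimum duration in seconds (default 40).
#' @param schedule A [light_schedule()].
#' @return Tibble `cage_id, start, duration (s), day, phase`.
#' @export
detect_rest_bouts <- function(immobility, bout_min = 40,
                              schedule = light_schedule()) {
  stopifnot(bout_min > 0)
  bouts <- immobility |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$timestamp), ]
      sec <- as.numeric(d$timestamp)
      v <- d$immobile
      v[is.na(v)] <- -1L
      # break runs at value changes and at grid gaps
      brk <- c(TRUE, v[-1] != v[-length(v)] | diff(sec) != 1)
      run_id <- cumsum(brk)
      starts <- which(brk)
      lens <- diff(c(starts, length(v) + 1L))
      keep <- v[starts] == 1L & lens >= bout_min
      tibble::tibble(
        start = d$timestamp[starts[keep]],
        duration = as.numeric(lens[keep])
      )
    }) |>
    dplyr::ungroup()
  if (nrow(bouts) == 0) {
    return(tibble::tibble(
      cage_id = character(), start = as.POSIXct(character(), tz = "UTC"),
      duration = double(), day = as.Date(character()),
      phase = factor(levels = c("light", "dark"))
    ))
  }
  ph <- assign_phases(dplyr::rename(bouts, timestamp = "start"), schedule)
  bouts$day <- ph$day
  bouts$phase <- ph$phase
  dplyr::select(bouts, "cage_id", "start", "duration", "day", "phase") |>
    dplyr::arrange(.data$cage_id, .data$start)
}

#' Time-weighted rest-bout duration histogram
#'
#' Partitions bouts into duration bins (default <5, 5-15, >15 min; the first
#' bin starts at the 40-s minimum, bins are left-closed) and weights each bin
#' by the total rest time it contains, normalized by the total rest time of
#' the phase, so weights per phase sum to 1 whenever any bout exists.
#' Respects dplyr grouping on `bouts` (e.g. per cage or per week) in addition
#' to `phase`.
#'
#' @param bouts Output of [detect_rest_bouts()], optionally grouped.
#' @param bins Interior bin edges in minutes (default `c(5, 15)`).
#' @param bout_min Lower edge of the first bin in seconds (default 40).
#' @return Tibble with grouping columns, `phase`, `bin`, `weight`,
#'   `total_rest_s`; empty phases get zero weights and flag `"no_bouts"`.
#' @export
time_weighted_histogram <- function(bouts, bins = c(5, 15), bout_min = 40) {
  stopifnot(!is.unsorted(bins, strictly = TRUE))
  gv <- dplyr::group_vars(bouts)
  edges <- c(bout_min / 60, bins, Inf)
  labs <- bin_labels(bins)
  tab <- bouts |>
    dplyr::mutate(bin = cut(.data$duration / 60, breaks = edges,
                            labels = labs, right = FALSE)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gv, "phase", "bin")))) |>
    dplyr::summarise(bin_rest_s = sum(.data$duration), .groups = "drop") |>
    complete_over_groups(
      gv,
      phase = factor(c("light", "dark"), levels = c("light", "dark")),
      bin = factor(labs, levels = labs),
      fill = list(bin_rest_s = 0)
    )
  tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gv, "phase")))) |>
    dplyr::mutate(
      total_rest_s = sum(.data$bin_rest_s),
      weight = ifelse(.data$total_rest_s > 0,
                      .data$bin_rest_s / .data$total_rest_s, 0),
      flag = ifelse(.data$total_rest_s > 0, "ok", "no_bouts")
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(gv), "phase", "bin", "weight", "total_rest_s", "flag") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(gv, "phase", "bin"))))
}

bin_labels <- function(bins) {
  k <- length(bins)
  c(
    sprintf("<%g min", bins[1]),
    if (k > 1) sprintf("%g-%g min", bins[-k], bins[-1]),
    sprintf(">%g min", bins[k])
  )
}

#' Fraction of rest time spent in long bouts
#'
#' The share of total rest time contributed by bouts longer than `threshold`
#' minutes (default 30 min), per phase and per any dplyr grouping on `bouts`.
#' Phases with bouts but none above threshold give 0; phases with no bouts
#' give 0 with flag `"no_bouts"`.
#'
#' @param bouts Output of [detect_rest_bouts()], optionally grouped.
#' @param threshold Duration threshold in minutes (default 30).
#' @return Tibble with grouping columns, `phase`, `long_fraction`,
#'   `total_rest_s`, `flag`.
#' @export
long_bout_fraction <- function(bouts, threshold = 30) {
  gv <- dplyr::group_vars(bouts)
  bouts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(gv, "phase")))) |>
    dplyr::summarise(
      total_rest_s = sum(.data$duration),
      long_rest_s = sum(.data$duration[.data$duration > threshold * 60]),
      .groups = "drop"
    ) |>
    complete_over_groups(
      gv,
      phase = factor(c("light", "dark"), levels = c("light", "dark")),
      fill = list(total_rest_s = 0, long_rest_s = 0)
    ) |>
    dplyr::mutate(
      long_fraction = ifelse(.data$total_rest_s > 0,
                             .data$long_rest_s / .data$total_rest_s, 0),
      flag = ifelse(.data$total_rest_s > 0, "ok", "no_bouts")
    ) |>
    dplyr::select(-"long_rest_s") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(gv, "phase"))))
}

# tidyr::complete over the cross of fixed level sets, nesting any grouping
# columns so only observed group combinations are expanded
complete_over_groups <- function(data, gv, ..., fill = list()) {
  if (length(gv) == 0) {
    tidyr::complete(data, ..., fill = fill)
  } else {
    tidyr::complete(data, tidyr::nesting(!!!rlang::syms(gv)), ..., fill = fill)
  }
}
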