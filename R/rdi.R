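#' Zero-phase Butterworth band-pass for minute-activity series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to a
#' regularly sampled series, parameterized by the period bounds of the
#' passband. For a per-minute series the defaults pass oscillations with
#' periods between `band_low_period` and `band_high_period` minutes and
#' remove the DC level and slow circadian trend. When `band_low_period` is at
#' or below twice the sampling interval the upper band edge coincides with
#' the Nyquist frequency and no discrete band-pass exists; the filter then
#' reduces to the realizable high-pass at `1/band_high_period` (trend/DC
#' removal), which is the defaults' behaviour for 1/min data.
#'
#' @param x Numeric series (regular sampling, no NAs).
#' @param band_low_period,band_high_period Passband period bounds, in units
#'   of `1/fs` samples (minutes for 1/min data).
#' @param order Butterworth order.
#' @param fs Sampling rate (samples per minute; default 1).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, band_low_period = 2, band_high_period = 120,
                            order = 2, fs = 1) {
  stopifnot(band_low_period > 0, band_high_period > band_low_period, order >= 1)
  if (length(x) <= 3 * order) {
    stop(sprintf("length error: series of length %d too short for order-%d filtering",
                 length(x), order), call. = FALSE)
  }
  if (anyNA(x)) stop("bandpass_filter: series must not contain NA", call. = FALSE)
  dsg <- design_bandpass(band_low_period, band_high_period, order, fs)
  apply_zero_phase(dsg, x)
}

design_bandpass <- function(band_low_period, band_high_period, order, fs = 1) {
  nyq <- fs / 2
  w_low <- (1 / band_high_period) / nyq
  w_high <- (1 / band_low_period) / nyq
  bf <- if (w_high >= 1) {
    signal::butter(order, w_low, type = "high")
  } else {
    signal::butter(order, c(w_low, w_high), type = "pass")
  }
  list(bf = bf, order = order, w_low = w_low)
}

# zero-phase application: demean, odd-reflect pad (long enough for the slow
# low-edge transient to die out), forward-backward filter, trim
apply_zero_phase <- function(dsg, x) {
  n <- length(x)
  x0 <- x - mean(x)
  pad <- min(n - 1, max(3 * (2 * dsg$order + 1), ceiling(6 / dsg$w_low)))
  xe <- c(2 * x0[1] - x0[(pad + 1):2], x0, 2 * x0[n] - x0[(n - 1):(n - pad)])
  b <- dsg$bf$b; a <- dsg$bf$a
  y <- as.numeric(stats::filter(xe, b, method = "convolution", sides = 1))
  y[seq_len(length(b) - 1)] <- cumsum_filter_head(xe, b)
  y <- iir_recurse(y, a)
  y <- rev(y)
  y2 <- as.numeric(stats::filter(y, b, method = "convolution", sides = 1))
  y2[seq_len(length(b) - 1)] <- cumsum_filter_head(y, b)
  y2 <- rev(iir_recurse(y2, a))
  y2[(pad + 1):(pad + n)]
}

# direct-form head terms where the convolution window is truncated
cumsum_filter_head <- function(x, b) {
  k <- length(b) - 1
  vapply(seq_len(k), function(i) sum(b[seq_len(i)] * x[i:1]), numeric(1))
}

# apply the AR (denominator) part: y[t] = x[t] - a[2] y[t-1] - ...
iir_recurse <- function(x, a) {
  if (length(a) <= 1) return(x)
  as.numeric(stats::filter(x, -a[-1], method = "recursive"))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' within Chebyshev distance `r` and A counts the same pairs still matching
#' when extended to length `m + 1`; self-matches are excluded. 0 means a
#' perfectly regular series (every template match persists); larger values
#' mean more irregularity. Degenerate counts are handled for pipeline use:
#' `B = 0` (no template matches at all) yields `NA` with flag `"undefined"`;
#' `A = 0` with `B > 0` yields the capped estimate `-ln(1/(B+1))` with flag
#' `"capped"`, avoiding infinities.
#'
#' @param x Numeric series, length > `m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance (absolute units, > 0).
#' @return A single number with attribute `flag` (`"ok"`, `"capped"` or
#'   `"undefined"`).
#' @examples
#' sample_entropy(rep(1, 100), m = 2, r = 0.2) # 0: perfectly regular
#' @export
sample_entropy <- function(x, m = 2, r) {
  m <- as.integer(m)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r <= 0) {
    stop("parameter error: r must be a single positive number", call. = FALSE)
  }
  if (length(x) <= m + 1) {
    stop("length error: need length(x) > m + 1", call. = FALSE)
  }
  if (anyNA(x)) stop("sample_entropy: series must not contain NA", call. = FALSE)
  cnt <- sampen_counts(as.numeric(x), m, r)
  if (cnt$B == 0) {
    return(structure(NA_real_, flag = "undefined"))
  }
  if (cnt$A == 0) {
    return(structure(-log(1 / (cnt$B + 1)), flag = "capped"))
  }
  structure(-log(cnt$A / cnt$B), flag = "ok")
}

#' Regularity Disruption Index per cage, day and phase
#'
#' The RDI of a 12-h phase is the sample entropy of the Butterworth
#' band-pass-filtered per-minute activity of that phase, with the tolerance
#' expressed as `samp_en_r` times the SD of the filtered segment (so light
#' and dark are each self-normalized, and the index is invariant to affine
#' rescaling of activity). RDI near 0 indicates minute activity levels that
#' are all very similar (consolidated, rest-like); a fragmented series in
#' which successive minutes differ irregularly gives a high RDI.
#'
#' Segments with more than 20% masked minutes are flagged `low_confidence`;
#' masked minutes are linearly interpolated before filtering. A constant
#' (zero-variance) filtered segment returns RDI 0.
#'
#' @param activity Activity tibble `timestamp, cage_id, activity` (per
#'   minute), e.g. from [activity_index()] or [simulate_cohort()].
#' @param schedule A [light_schedule()].
#' @param config An [analysis_config()].
#' @return Tibble `cage_id, day, phase, rdi, flag`.
#' @export
compute_rdi <- function(activity, schedule = light_schedule(),
                        config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  dsg <- design_bandpass(config$band_low_period, config$band_high_period,
                         config$filter_order)
  assign_phases(activity, schedule) |>
    dplyr::arrange(.data$cage_id, .data$timestamp) |>
    dplyr::group_by(.data$cage_id, .data$day, .data$phase) |>
    dplyr::group_modify(function(d, key) {
      res <- rdi_one_segment(d$activity, config, dsg)
      tibble::tibble(rdi = res$rdi, flag = res$flag)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cage_id, .data$day, .data$phase)
}

rdi_one_segment <- function(x, config, dsg = NULL) {
  if (is.null(dsg)) {
    dsg <- design_bandpass(config$band_low_period, config$band_high_period,
                           config$filter_order)
  }
  mask_frac <- mean(is.na(x))
  flag <- if (mask_frac > 0.2) "low_confidence" else "ok"
  if (all(is.na(x))) {
    return(list(rdi = NA_real_, flag = "all_masked"))
  }
  x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  if (length(x) <= max(3 * config$filter_order, config$samp_en_m + 1)) {
    return(list(rdi = NA_real_, flag = "too_short"))
  }
  f <- apply_zero_phase(dsg, x)
  s <- stats::sd(f)
  if (!is.finite(s) || s < 1e-12) {
    return(list(rdi = 0, flag = flag))
  }
  v <- sample_entropy(f, m = config$samp_en_m, r = config$samp_en_r * s)
  vf <- attr(v, "flag")
  if (vf != "ok") flag <- if (flag == "ok") vf else paste(flag, vf, sep = ";")
  list(rdi = as.numeric(v), flag = flag)
}
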