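#' Detect electrode activations from raw capacitance
#'
#' An electrode counts as activated in a comparison window when the absolute
#' difference between two consecutive capacitance samples exceeds the fixed
#' threshold `lambda`, chosen to separate sensor noise from animal movement.
#' One output row is produced per consecutive sample pair (labelled with the
#' first sample's timestamp); masked samples propagate `NA`.
#'
#' @param capacitance Tibble `timestamp, cage_id, e01..e12` (see
#'   [read_capacitance_csv()]).
#' @param lambda Activation threshold (> 0).
#' @return Tibble `timestamp, cage_id, e01..e12` of 0/1/NA activations.
#' @export
detect_activations <- function(capacitance, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda <= 0) {
    stop("parameter error: lambda must be a single positive number", call. = FALSE)
  }
  ecols <- grep("^e[0-9]{2}$", names(capacitance), value = TRUE)
  stopifnot(length(ecols) == 12)
  capacitance |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 2) stop("need at least 2 samples per cage", call. = FALSE)
      m <- as.matrix(d[ecols])
      act <- abs(m[-1, , drop = FALSE] - m[-n, , drop = FALSE]) > lambda
      out <- tibble::as_tibble(act * 1L)
      names(out) <- ecols
      dplyr::bind_cols(tibble::tibble(timestamp = d$timestamp[-n]), out)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("timestamp", "cage_id", dplyr::all_of(ecols))
}

#' Per-minute graded activity index (activation density)
#'
#' The raw index for a minute is the fraction of activated
#' (electrode, comparison-window) pairs among all unmasked pairs in that
#' minute, a number in `[0, 1]`; comparison windows are attributed to the
#' minute of their first sample. The smoothed index is a centred moving
#' average over `smooth_window` minutes (NA-aware). Masked pairs are removed
#' from the denominator; a fully masked minute is `NA`.
#'
#' @param activations Output of [detect_activations()].
#' @param fs Sampling rate in Hz (only used for documentation of the expected
#'   pair count; the denominator always counts actual unmasked pairs).
#' @param smooth_window Centred moving-average width in minutes (odd).
#' @return Tibble `timestamp, cage_id, activity, activity_raw` at 1-min
#'   resolution (`activity` is the smoothed index).
#' @export
activity_index <- function(activations, fs = 4, smooth_window = 3) {
  smooth_window <- as.integer(smooth_window)
  stopifnot(smooth_window >= 1)
  ecols <- grep("^e[0-9]{2}$", names(activations), value = TRUE)
  activations |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[ecols])
      minute <- (as.numeric(d$timestamp) %/% 60) * 60
      hits <- rowSums(m, na.rm = TRUE)
      navail <- rowSums(!is.na(m))
      agg_hits <- rowsum(hits, minute)
      agg_n <- rowsum(navail, minute)
      raw <- ifelse(agg_n > 0, agg_hits / agg_n, NA_real_)
      mins <- as.numeric(rownames(agg_hits))
      o <- order(mins)
      raw <- as.numeric(raw)[o]
      tibble::tibble(
        timestamp = as.POSIXct(mins[o], origin = "1970-01-01", tz = "UTC"),
        activity = moving_average(raw, smooth_window),
        activity_raw = raw
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("timestamp", "cage_id", "activity", "activity_raw")
}

# centred NA-aware moving average; edges use the available part of the window
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- width %/% 2
  n <- length(x)
  xs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  ns <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- xs[hi + 1L] - xs[lo]
  k <- ns[hi + 1L] - ns[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Per-second binary immobility series
#'
#' Rest scoring uses the lowest usable activation threshold so that even very
#' small or slow movements of either animal count as activity: capacitance is
#' averaged into 1-s windows per electrode, and a second is immobile (1) iff
#' no electrode's difference between its average and the previous second's
#' average exceeds `lambda_immobility` (default 1.25). A 1 therefore means
#' both co-housed mice were immobile. The first second of a record has no
#' predecessor and is dropped; seconds whose comparison involves masked data
#' and shows no exceedance are `NA`.
#'
#' @param capacitance Tibble `timestamp, cage_id, e01..e12`.
#' @param lambda_immobility Threshold on consecutive 1-s average differences
#'   (default 1.25).
#' @return Tibble `timestamp, cage_id, immobile` at 1-s resolution.
#' @export
immobility_series <- function(capacitance, lambda_immobility = 1.25) {
  if (lambda_immobility <= 0) stop("parameter error: lambda_immobility must be > 0", call. = FALSE)
  ecols <- grep("^e[0-9]{2}$", names(capacitance), value = TRUE)
  stopifnot(length(ecols) == 12)
  capacitance |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      m <- as.matrix(d[ecols])
      sec <- as.numeric(d$timestamp) %/% 1
      usec <- sort(unique(sec))
      sums <- rowsum(ifelse(is.na(m), 0, m), sec)
      cnts <- rowsum((!is.na(m)) * 1L, sec)
      means <- ifelse(cnts > 0, sums / cnts, NA_real_)
      o <- order(as.numeric(rownames(sums)))
      means <- means[o, , drop = FALSE]
      nsec <- length(usec)
      if (nsec < 2) stop("need at least 2 seconds of data", call. = FALSE)
      dm <- abs(means[-1, , drop = FALSE] - means[-nsec, , drop = FALSE])
      # adjacent-grid seconds only; a hole in the grid masks the comparison
      contiguous <- diff(usec) == 1
      exceed <- rowSums(dm > lambda_immobility, na.rm = TRUE) > 0
      any_na <- rowSums(is.na(dm)) > 0
      imm <- unname(ifelse(exceed, 0L, ifelse(any_na, NA_integer_, 1L)))
      imm[!contiguous & !exceed] <- NA_integer_
      tibble::tibble(
        timestamp = as.POSIXct(usec[-1], origin = "1970-01-01", tz = "UTC"),
        immobile = imm
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("timestamp", "cage_id", "immobile")
}
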