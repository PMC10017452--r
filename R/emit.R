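#' Emit synthetic raw capacitance from an immobility series
#'
#' Inverse of the activation stage for testing purposes: given a per-second
#' immobility series, synthesizes a 12-electrode capacitance trace sampled at
#' `fs` Hz whose activation structure reproduces it. Immobile seconds carry
#' only sub-threshold Gaussian jitter; each active second makes 1-3 randomly
#' chosen electrodes jump well above both the standard and the immobility
#' thresholds. This is a synthetic stand-in for the proprietary sensor
#' stream, useful to exercise [detect_activations()], [activity_index()] and
#' [immobility_series()] end to end.
#'
#' @param immobility Tibble `timestamp, cage_id, immobile` (1-s resolution;
#'   the first emitted second is prepended as a warm-up so the round trip
#'   reproduces the input from its second value on). Note the inherent
#'   one-second smear of consecutive-mean immobility scoring: a movement in
#'   second `s` elevates that second's 1-s mean, so both the `s-1 -> s` and
#'   the `s -> s+1` comparisons exceed threshold and an immobile second
#'   directly after an active one is scored mobile. Round-trip checks should
#'   therefore compare seconds whose predecessor is also immobile.
#' @param fs Sampling rate in Hz (default 4).
#' @param lambda Standard activation threshold the trace should exceed when
#'   active (default 5).
#' @param jitter_sd SD of the sub-threshold sensor noise (default 0.05).
#' @param seed Integer seed.
#' @return Capacitance tibble `timestamp, cage_id, e01..e12`.
#' @export
emit_capacitance <- function(immobility, fs = 4, lambda = 5,
                             jitter_sd = 0.05, seed = 1) {
  stopifnot(fs >= 1, lambda > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  step <- 1 / fs
  jump <- 4 * max(lambda, 1.25 * 2)
  immobility |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$timestamp), ]
      n_sec <- nrow(d) + 1L # warm-up second before the first scored one
      n_samp <- n_sec * round(fs)
      base <- matrix(100, n_samp, 12) +
        matrix(rnorm(n_samp * 12, 0, jitter_sd), n_samp, 12)
      active_sec <- which(d$immobile == 0L) + 1L # offset for warm-up
      for (s in active_sec) {
        el <- sample.int(12, sample.int(3, 1))
        at <- (s - 1L) * round(fs) + sample.int(round(fs), 1)
        # a one-sample pulse: large per-sample differences inside the second
        # and a 1-s mean shift of jump/fs, both above threshold
        base[at, el] <- base[at, el] + jump
      }
      t0 <- as.numeric(d$timestamp[1]) - 1
      out <- tibble::as_tibble(base, .name_repair = "minimal")
      names(out) <- sprintf("e%02d", 1:12)
      dplyr::bind_cols(
        tibble::tibble(timestamp = as.POSIXct(
          t0 + (seq_len(n_samp) - 1) * step, origin = "1970-01-01", tz = "UTC"
        )),
        out
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("timestamp", "cage_id", dplyr::everything())
}
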