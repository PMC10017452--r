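# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

T0 <- as.POSIXct("2021-01-11 07:00:00", tz = "UTC") # a lights-on instant

minute_series <- function(values, cage_id = "C01", start = T0) {
  tibble::tibble(
    timestamp = start + 60 * (seq_along(values) - 1),
    cage_id = cage_id,
    activity = values
  )
}

second_series <- function(values, cage_id = "C01", start = T0) {
  tibble::tibble(
    timestamp = start + (seq_along(values) - 1),
    cage_id = cage_id,
    immobile = as.integer(values)
  )
}

# O(N^2) sample entropy, Richman & Moorman counting, independent of src/
naive_sample_entropy <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  if (A == 0) return(-log(1 / (B + 1)))
  -log(A / B)
}

# run-length brute force for rest bouts on a 0/1/NA vector
naive_bouts <- function(v, bout_min) {
  out <- list()
  i <- 1; n <- length(v)
  while (i <= n) {
    if (!is.na(v[i]) && v[i] == 1L) {
      j <- i
      while (j < n && !is.na(v[j + 1]) && v[j + 1] == 1L) j <- j + 1
      if (j - i + 1 >= bout_min) out[[length(out) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), len = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# exhaustive least-active-hour search over a 1440-minute day
naive_lah <- function(x, max_masked = 10) {
  best <- NULL
  for (s in 0:(length(x) - 60)) {
    w <- x[(s + 1):(s + 60)]
    if (sum(is.na(w)) > max_masked || all(is.na(w))) next
    mu <- mean(w, na.rm = TRUE)
    if (is.null(best) || mu < best$mean) best <- list(start = s, mean = mu)
  }
  best
}

# direct per-hour percent-zero count on a binary vector starting at lights-on
naive_pct_zero <- function(v) {
  n_h <- length(v) %/% 3600
  vapply(seq_len(n_h), function(h) {
    w <- v[((h - 1) * 3600 + 1):(h * 3600)]
    if (all(is.na(w))) return(NA_real_)
    100 * mean(w, na.rm = TRUE)
  }, numeric(1))
}

# brute-force time-weighted histogram weights for one phase
naive_hist_weights <- function(durations_s, edges_min) {
  br <- c(-Inf, edges_min * 60, Inf)
  tot <- sum(durations_s)
  w <- vapply(seq_len(length(br) - 1), function(k) {
    sum(durations_s[durations_s >= br[k] & durations_s < br[k + 1]])
  }, numeric(1))
  w / tot
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
naive_wilcoxon_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  robs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  rk <- rank(pooled)
  stats <- apply(combos, 2, function(idx) sum(rk[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(stats - mu) >= abs(robs - mu) - 1e-9)
}

# analytic squared magnitude of the digital Butterworth band-pass designed by
# bilinear transform (filtfilt applies the magnitude twice)
butter_bp_gain <- function(f, p_short, p_long, order, fs = 1) {
  O <- function(fr) tan(pi * fr / fs)
  O1 <- O(1 / p_long); O2 <- O(1 / p_short); Of <- O(f)
  1 / sqrt(1 + ((Of^2 - O1 * O2) / ((O2 - O1) * Of))^(2 * order))
}

butter_hp_gain <- function(f, p_long, order, fs = 1) {
  O <- function(fr) tan(pi * fr / fs)
  1 / sqrt(1 + (O(1 / p_long) / O(f))^(2 * order))
}

# amplitude of a sinusoidal steady state measured away from the edges
measured_amplitude <- function(y) {
  core <- y[round(length(y) * 0.3):round(length(y) * 0.7)]
  sqrt(2 * mean(core^2))
}
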