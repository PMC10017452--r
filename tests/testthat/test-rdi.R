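test_that("sample entropy matches the naive O(N^2) oracle", {
  # the repeating [1,2,3] pattern, m = 2, r = 0.5
  x <- rep(c(1, 2, 3), 4)
  expect_equal(as.numeric(sample_entropy(x, 2, 0.5)),
               naive_sample_entropy(x, 2, 0.5), tolerance = 1e-12)

  # random instances, several lengths and tolerances
  set.seed(101)
  for (i in 1:20) {
    n <- sample(30:150, 1)
    x <- switch(sample(3, 1),
      runif(n), rnorm(n), round(runif(n), 1) # ties included
    )
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.5) * sd(x)
    expect_equal(as.numeric(sample_entropy(x, m, r)),
                 naive_sample_entropy(x, m, r), tolerance = 1e-12)
  }
})

test_that("sample entropy handles degenerate and invalid inputs as defined", {
  # constant series is perfectly regular
  v <- sample_entropy(rep(2, 100), 2, 0.2)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "flag"), "ok")

  # no template matches at all: undefined
  v <- sample_entropy(c(0, 10, 20, 40, 80, 160, 320), 2, 0.5)
  expect_true(is.na(as.numeric(v)))
  expect_equal(attr(v, "flag"), "undefined")

  # matches at m but none at m+1: capped at -ln(1/(B+1))
  v <- sample_entropy(c(0, 0, 10, 20, 30), 1, 0.5) # B = 1 (the two 0s), A = 0
  expect_equal(attr(v, "flag"), "capped")
  expect_equal(as.numeric(v), log(2))

  expect_error(sample_entropy(1:10, 2, r = 0), "parameter")
  expect_error(sample_entropy(1:3, 2, r = 0.1), "length")
})

test_that("sample entropy is invariant to affine transforms when r scales with SD", {
  set.seed(102)
  x <- rnorm(300)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    y <- a * x + b
    expect_equal(
      as.numeric(sample_entropy(x, 2, 0.2 * sd(x))),
      as.numeric(sample_entropy(y, 2, 0.2 * sd(y))),
      tolerance = 1e-9
    )
  }
})

test_that("band-pass removes DC and matches the analytic Butterworth gain", {
  # constant input: exactly zero output
  expect_lt(max(abs(bandpass_filter(rep(7.7, 600)))), 1e-8)

  # forward-backward filtering applies the squared magnitude response
  for (probe in list(c(per = 8), c(per = 30), c(per = 60), c(per = 300))) {
    f <- 1 / probe[["per"]]
    x <- sin(2 * pi * f * (1:6000))
    y <- bandpass_filter(x, band_low_period = 4, band_high_period = 120, order = 2)
    expect_equal(measured_amplitude(y),
                 butter_bp_gain(f, 4, 120, 2)^2,
                 tolerance = 0.01)
  }
  # default configuration degrades to the high-pass at 1/120
  x <- sin(2 * pi * (1:6000) / 300)
  y <- bandpass_filter(x, band_low_period = 2, band_high_period = 120, order = 2)
  expect_equal(measured_amplitude(y), butter_hp_gain(1 / 300, 120, 2)^2,
               tolerance = 0.01)

  expect_error(bandpass_filter(rnorm(5), order = 2), "length")
})

test_that("filtering is zero-phase: reversal commutes with the filter", {
  set.seed(103)
  x <- cumsum(rnorm(720))
  a <- bandpass_filter(x, 4, 120, 2)
  b <- rev(bandpass_filter(rev(x), 4, 120, 2))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("RDI is zero for constant phases and higher for fragmented activity", {
  sched <- light_schedule()
  cfg <- analysis_config()
  # constant activity in both phases
  act <- minute_series(rep(0.3, 1440))
  r <- compute_rdi(act, sched, cfg)
  expect_equal(nrow(r), 2)
  expect_true(all(r$rdi == 0))

  # stochastic fragmentation vs consolidation at matched totals: rapid
  # irregular switching between high and low minutes has larger entropy than
  # the same total activity in a few consolidated blocks
  set.seed(104)
  frag_wins <- 0
  for (i in 1:20) {
    frag <- ifelse(runif(720) < 0.5, 0.6, 0) * (1 + 0.1 * rnorm(720))
    blocks <- rep(rep(c(0.6, 0), 6), each = 60)[1:720] * (1 + 0.1 * rnorm(720))
    d <- tibble::tibble(
      timestamp = rep(T0 + 60 * (0:719), 2),
      cage_id = rep(c("FRAG", "CONS"), each = 720),
      activity = pmax(0, c(frag, blocks))
    )
    r <- compute_rdi(d, sched, cfg)
    frag_wins <- frag_wins +
      (r$rdi[r$cage_id == "FRAG"] > r$rdi[r$cage_id == "CONS"])
  }
  expect_gte(frag_wins, 19)
})

test_that("consolidated-rest cages score lower dark RDI than fragmented cages", {
  # same stationary dark rest fraction, very different dwell scales
  base <- simulation_params(weeks = 2 / 7, cage_change_every = 99)
  consolidated <- simulation_params(
    weeks = 2 / 7, dwell_rest_median = c(light = 90, dark = 60) * 8,
    cage_change_every = 99
  )
  wins <- 0
  for (seed in 1:12) {
    a <- simulate_cage(base, "M", "WT", "FRAG", seed)
    b <- simulate_cage(consolidated, "M", "WT", "CONS", seed + 500)
    ra <- compute_rdi(a$activity)
    rb <- compute_rdi(b$activity)
    mdark <- function(r) mean(r$rdi[r$phase == "dark"], na.rm = TRUE)
    wins <- wins + (mdark(rb) < mdark(ra))
  }
  expect_gte(wins, 11)
})
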