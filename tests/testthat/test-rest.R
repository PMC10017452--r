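test_that("percent zero per hour equals direct counting", {
  # all-immobile hour and a 50% hour
  v <- c(rep(1L, 3600), rep(c(1L, 0L), 1800))
  pz <- percent_zero_per_hour(second_series(v))
  expect_equal(pz$pct_zero, c(100, 50))
  expect_equal(pz$hour, c(1L, 2L))
  expect_equal(as.character(pz$phase), c("light", "light"))

  # random days match the brute-force per-hour count
  set.seed(201)
  v <- as.integer(runif(26 * 3600) < 0.6)
  v[sample(length(v), 500)] <- NA
  pz <- percent_zero_per_hour(second_series(v))
  expect_equal(pz$pct_zero[1:24], naive_pct_zero(v)[1:24])
  # hours 25, 26 belong to the next day
  expect_equal(pz$day[25], pz$day[1] + 1)
  expect_equal(pz$hour[25:26], c(1L, 2L))
  # dark phase hours 13..24
  expect_equal(as.character(pz$phase[13]), "dark")
})

test_that("least active hour is the exhaustive argmin with earliest-tie rule", {
  # forced minimum at minutes 300..359
  x <- rep(1, 1440); x[301:360] <- 0
  lah <- least_active_hour(minute_series(x))
  expect_equal(lah$start_minute, 300)
  expect_equal(lah$mean_activity, 0)
  expect_equal(as.character(lah$phase), "light")

  # constant series: tie broken at the earliest start
  lah <- least_active_hour(minute_series(rep(0.5, 1440)))
  expect_equal(lah$start_minute, 0)

  # random days equal the brute-force search
  set.seed(202)
  for (i in 1:10) {
    x <- runif(1440)
    x[sample(1440, 30)] <- NA
    lah <- least_active_hour(minute_series(x))
    ref <- naive_lah(x)
    expect_equal(lah$start_minute, ref$start)
    expect_equal(lah$mean_activity, ref$mean)
  }

  # a window starting in the dark phase is labelled dark
  x <- rep(1, 1440); x[801:860] <- 0
  lah <- least_active_hour(minute_series(x))
  expect_equal(as.character(lah$phase), "dark")
})

test_that("least-active-hour mean never exceeds the daily mean", {
  set.seed(203)
  for (i in 1:5) {
    x <- runif(1440)^2
    lah <- least_active_hour(minute_series(x))
    expect_lte(lah$mean_activity, mean(x))
  }
})

test_that("least-active-hour histogram and dark fraction summarize starts", {
  lah <- tibble::tibble(
    cage_id = "C01", day = as.Date("2021-01-11") + 0:99,
    start_minute = c(rep(120, 90), rep(800, 10)),
    mean_activity = 0,
    phase = factor(rep(c("light", "dark"), c(90, 10)), levels = c("light", "dark"))
  )
  h <- least_active_hour_histogram(lah)
  expect_equal(sort(h$bin_start_minute), c(120, 780))
  expect_equal(h$n[h$bin_start_minute == 120], 90)
  expect_equal(sum(h$prop), 1)
  expect_equal(lah_dark_fraction(lah)$dark_fraction, 0.10)
})

test_that("rest bouts are maximal >= 40 s runs matching an RLE oracle", {
  # 39 s run: no bout; 50 s run: one bout
  v <- c(rep(0L, 10), rep(1L, 39), rep(0L, 5), rep(1L, 50), rep(0L, 10))
  b <- detect_rest_bouts(second_series(v), 40)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 50)

  # random binary series equals the brute-force run scanner (masks break runs)
  set.seed(204)
  for (i in 1:10) {
    v <- as.integer(runif(5000) < 0.8)
    v[sample(5000, 50)] <- NA
    imm <- second_series(v)
    b <- detect_rest_bouts(imm, 40)
    ref <- naive_bouts(v, 40)
    expect_equal(nrow(b), nrow(ref))
    if (nrow(ref) > 0) {
      expect_equal(as.numeric(b$start) - as.numeric(T0), ref$start - 1)
      expect_equal(b$duration, as.numeric(ref$len))
    }
  }
})

test_that("bout phase attribution follows the onset second", {
  # bout straddling lights-off (dark starts at second 43200 post lights-on)
  v <- rep(0L, 43260)
  v[(43200 - 59):43260] <- 1L # starts 60 s before lights-off, continues after
  b <- detect_rest_bouts(second_series(v), 40)
  expect_equal(nrow(b), 1)
  expect_equal(as.character(b$phase), "light")
})

test_that("bout time is conserved and monotone in the threshold", {
  set.seed(205)
  v <- as.integer(runif(20000) < 0.7)
  imm <- second_series(v)
  # at threshold 1 every immobile second sits in exactly one bout
  b1 <- detect_rest_bouts(imm, 1)
  expect_equal(sum(b1$duration), sum(v == 1L))
  # raising the threshold never increases count or total time
  thresholds <- c(1, 10, 40, 120, 600)
  res <- sapply(thresholds, function(th) {
    b <- detect_rest_bouts(imm, th)
    c(n = nrow(b), tot = sum(b$duration))
  })
  expect_true(all(diff(res["n", ]) <= 0))
  expect_true(all(diff(res["tot", ]) <= 0))
})

test_that("time-weighted histogram weights are normalized bin rest times", {
  mk_bouts <- function(durations_min, phase = "dark") {
    tibble::tibble(
      cage_id = "C01",
      start = T0 + seq_along(durations_min) * 7200,
      duration = durations_min * 60,
      day = as.Date("2021-01-11"),
      phase = factor(phase, levels = c("light", "dark"))
    )
  }
  # single 10-min dark bout: weights (0, 1, 0)
  h <- time_weighted_histogram(mk_bouts(10))
  expect_equal(h$weight[h$phase == "dark"], c(0, 1, 0))
  expect_equal(h$weight[h$phase == "light"], c(0, 0, 0))
  expect_equal(h$flag[h$phase == "light"], rep("no_bouts", 3))

  # bouts of 4 and 16 min: weights (0.2, 0, 0.8)
  h <- time_weighted_histogram(mk_bouts(c(4, 16)))
  expect_equal(h$weight[h$phase == "dark"], c(0.2, 0, 0.8))

  # random bout sets match brute-force summation and sum to 1
  set.seed(206)
  for (i in 1:10) {
    d <- exp(runif(30, log(40 / 60), log(40))) # minutes, 40 s .. 40 min
    h <- time_weighted_histogram(mk_bouts(d))
    w <- h$weight[h$phase == "dark"]
    expect_equal(w, naive_hist_weights(d * 60, c(5, 15)), tolerance = 1e-12)
    expect_equal(sum(w), 1)
  }
})

test_that("long-bout fraction equals the direct ratio", {
  mk <- function(durations_min) {
    tibble::tibble(
      cage_id = "C01", start = T0 + seq_along(durations_min) * 3600,
      duration = durations_min * 60, day = as.Date("2021-01-11"),
      phase = factor("light", levels = c("light", "dark"))
    )
  }
  lb <- long_bout_fraction(mk(c(31, 1)))
  expect_equal(lb$long_fraction[lb$phase == "light"], 31 / 32)
  lb <- long_bout_fraction(mk(c(29, 5, 10)))
  expect_equal(lb$long_fraction[lb$phase == "light"], 0)
  set.seed(207)
  for (i in 1:5) {
    d <- exp(runif(20, log(1), log(50)))
    lb <- long_bout_fraction(mk(d))
    expect_equal(lb$long_fraction[lb$phase == "light"],
                 sum(d[d > 30]) / sum(d), tolerance = 1e-12)
  }
})
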