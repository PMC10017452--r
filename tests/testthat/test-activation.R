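make_cap <- function(mat, fs = 4, cage_id = "C01", start = T0) {
  colnames(mat) <- sprintf("e%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(
      timestamp = start + (seq_len(nrow(mat)) - 1) / fs,
      cage_id = cage_id
    ),
    tibble::as_tibble(mat)
  )
}

test_that("activation detection follows the |delta| > lambda rule exactly", {
  # constant trace: no activations
  cap <- make_cap(matrix(100, 40, 12))
  acts <- detect_activations(cap, lambda = 5)
  expect_equal(nrow(acts), 39)
  expect_true(all(as.matrix(acts[sprintf("e%02d", 1:12)]) == 0))

  # a single 2*lambda jump on electrode 3 between samples 10 and 11
  m <- matrix(100, 40, 12)
  m[11:40, 3] <- 110
  acts <- detect_activations(make_cap(m), lambda = 5)
  am <- as.matrix(acts[sprintf("e%02d", 1:12)])
  expect_equal(sum(am), 1)
  expect_equal(unname(which(am == 1, arr.ind = TRUE)[1, ]), c(10L, 3L))

  # random trace equals the explicit double-loop oracle
  set.seed(11)
  m <- matrix(rnorm(50 * 12, 100, 3), 50, 12)
  lam <- 2.5
  acts <- detect_activations(make_cap(m), lam)
  am <- as.matrix(acts[sprintf("e%02d", 1:12)])
  ref <- matrix(NA_integer_, 49, 12)
  for (i in 1:49) for (e in 1:12) {
    ref[i, e] <- as.integer(abs(m[i + 1, e] - m[i, e]) > lam)
  }
  expect_equal(am, ref, ignore_attr = TRUE)

  expect_error(detect_activations(cap, lambda = 0), "lambda")
  expect_error(detect_activations(cap, lambda = -1), "lambda")
})

test_that("activity index is activation density with the documented denominator", {
  # one activation within a full interior minute at 4 Hz: 12 * 240 pairs
  m <- matrix(100, 4 * 180, 12) # three minutes
  m[4 * 60 + 30, 5] <- 200
  m[4 * 60 + 31, 5] <- 100
  acts <- detect_activations(make_cap(m), lambda = 5)
  ai <- activity_index(acts, fs = 4, smooth_window = 1)
  # the jump up and back down gives two activated pairs in minute 2
  expect_equal(ai$activity_raw[2], 2 / 2880)
  expect_equal(ai$activity_raw[1], 0)

  # all-zero matrix gives zero activity everywhere
  acts0 <- detect_activations(make_cap(matrix(1, 480, 12)), lambda = 5)
  expect_true(all(activity_index(acts0, fs = 4)$activity_raw == 0))
})

test_that("smoothed index equals a brute-force centred moving average", {
  set.seed(5)
  raw <- runif(30)
  raw[c(4, 17)] <- NA
  sm <- cagerest:::moving_average(raw, 3)
  for (i in seq_along(raw)) {
    w <- raw[max(1, i - 1):min(length(raw), i + 1)]
    expect_equal(sm[i], mean(w, na.rm = TRUE))
  }
})

test_that("immobility scoring compares consecutive 1-s average windows", {
  # flat capacitance: fully immobile (first second dropped)
  cap <- make_cap(matrix(100, 4 * 10, 12))
  imm <- immobility_series(cap)
  expect_equal(nrow(imm), 9)
  expect_true(all(imm$immobile == 1))

  # a step of 2.0 > 1.25 in one electrode's 1-s mean breaks that second
  m <- matrix(100, 4 * 10, 12)
  m[(4 * 5 + 1):(4 * 10), 7] <- 102 # step at second 6
  imm <- immobility_series(make_cap(m))
  expect_equal(imm$immobile[5], 0L) # second 6 vs second 5
  expect_equal(sum(imm$immobile == 0L), 1)

  # noisy trace equals the brute-force 1-s-average comparison
  set.seed(12)
  m <- matrix(rnorm(4 * 30 * 12, 100, 1), 4 * 30, 12)
  imm <- immobility_series(make_cap(m), lambda_immobility = 1.25)
  ref <- vapply(2:30, function(s) {
    mu_prev <- colMeans(m[(4 * (s - 2) + 1):(4 * (s - 1)), ])
    mu_cur <- colMeans(m[(4 * (s - 1) + 1):(4 * s), ])
    as.integer(all(abs(mu_cur - mu_prev) <= 1.25))
  }, integer(1))
  expect_equal(imm$immobile, ref, ignore_attr = TRUE)
})

test_that("activation counts and mobility are monotone in lambda", {
  set.seed(13)
  m <- matrix(rnorm(4 * 60 * 12, 100, 2), 4 * 60, 12)
  cap <- make_cap(m)
  lambdas <- c(0.5, 1.25, 2.5, 5, 10)
  n_act <- sapply(lambdas, function(l) {
    sum(as.matrix(detect_activations(cap, l)[sprintf("e%02d", 1:12)]), na.rm = TRUE)
  })
  expect_true(all(diff(n_act) <= 0))
  n_mobile <- sapply(lambdas, function(l) {
    sum(immobility_series(cap, l)$immobile == 0L, na.rm = TRUE)
  })
  expect_true(all(diff(n_mobile) <= 0))
})

test_that("activity index is invariant to electrode permutation", {
  set.seed(14)
  m <- matrix(rnorm(4 * 120 * 12, 100, 2), 4 * 120, 12)
  a1 <- activity_index(detect_activations(make_cap(m), 2), fs = 4)
  a2 <- activity_index(detect_activations(make_cap(m[, sample(12)]), 2), fs = 4)
  expect_equal(a1$activity_raw, a2$activity_raw)
})

test_that("synthetic capacitance emission inverts to the immobility input", {
  set.seed(15)
  v <- as.integer(runif(240) < 0.7)
  imm <- second_series(v, start = T0 + 1)
  cap <- emit_capacitance(imm, fs = 4, lambda = 5, seed = 21)
  back <- immobility_series(cap, 1.25)
  j <- dplyr::inner_join(imm, back, by = c("timestamp", "cage_id"),
                         suffix = c("_true", "_rt"))
  # active seconds always score mobile
  expect_true(all(j$immobile_rt[j$immobile_true == 0L] == 0L))
  # immobile seconds whose predecessor is immobile score immobile
  prev <- c(NA_integer_, v[-length(v)])
  ok <- j$immobile_true == 1L & prev == 1L & !is.na(prev)
  expect_true(all(j$immobile_rt[ok] == 1L))
})
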