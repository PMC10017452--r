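test_that("phase labels partition the day with lights-on anchoring", {
  s <- light_schedule()
  d <- tibble::tibble(timestamp = T0 + 60 * (0:1439))
  ph <- assign_phases(d, s)
  # sample at lights-on is LIGHT hour 0; at lights-off DARK hour 12
  expect_equal(as.character(ph$phase[1]), "light")
  expect_equal(ph$hour[1], 0L)
  expect_equal(as.character(ph$phase[721]), "dark")
  expect_equal(ph$hour[721], 12L)
  expect_equal(unname(table(ph$phase)), c(720L, 720L), ignore_attr = TRUE)
  # the whole 24 h block is one analysis day even past midnight
  expect_length(unique(ph$day), 1)
  # pre-lights-on samples belong to the previous day
  before <- assign_phases(tibble::tibble(timestamp = T0 - 60), s)
  expect_equal(as.numeric(ph$day[1] - before$day), 1)
})

test_that("capacitance CSV round-trips and flags gaps as masked samples", {
  set.seed(41)
  n <- 64
  cap <- tibble::tibble(
    timestamp = T0 + (0:(n - 1)) / 4,
    cage_id = "C01"
  )
  for (e in sprintf("e%02d", 1:12)) cap[[e]] <- round(rnorm(n, 100), 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_capacitance_csv(cap, f)
  rt <- read_capacitance_csv(f, fs = 4)
  expect_equal(nrow(rt), n)
  expect_equal(rt$e07, cap$e07, tolerance = 1e-12)
  expect_equal(as.numeric(rt$timestamp), as.numeric(cap$timestamp), tolerance = 1e-6)

  # a 2-minute hole at 4 Hz leaves 480 masked sample slots
  gap <- dplyr::bind_rows(
    cap[1:20, ], # up to 4.75 s
    dplyr::mutate(cap[1:20, ], timestamp = timestamp + 125) # resumes at 125 s
  )
  write_capacitance_csv(gap, f)
  rt2 <- read_capacitance_csv(f, fs = 4)
  expect_equal(sum(is.na(rt2$e01)), 480L)

  # 11 electrode columns is a format error
  bad <- dplyr::select(cap, -"e12")
  write_capacitance_csv(bad, f)
  expect_error(read_capacitance_csv(f, fs = 4), "12 electrode")

  # non-monotone timestamps are a data error
  swapped <- cap
  swapped$timestamp[2:3] <- swapped$timestamp[3:2]
  write_capacitance_csv(swapped, f)
  expect_error(read_capacitance_csv(f, fs = 4), "non-monotone")
})

test_that("activity and metadata tables round-trip value-identically", {
  act <- minute_series(runif(120))
  f <- withr::local_tempfile(fileext = ".csv")
  write_activity_csv(act, f)
  rt <- read_activity_csv(f)
  expect_equal(rt$activity, act$activity, tolerance = 1e-12)
  expect_equal(as.numeric(rt$timestamp), as.numeric(act$timestamp))

  md <- tibble::tibble(
    cage_id = c("C01", "C02"), genotype = c("WT", "MUT"), sex = c("F", "F"),
    n_animals = 2L, cohort = "K1",
    cage_change_dates = list(as.Date("2021-01-11") + c(0, 7), as.Date(character()))
  )
  write_cage_metadata(md, f)
  rt <- read_cage_metadata(f)
  expect_equal(rt$cage_change_dates[[1]], md$cage_change_dates[[1]])
  expect_length(rt$cage_change_dates[[2]], 0)
  expect_equal(rt$genotype, md$genotype)
})

test_that("exclude_days removes change days, is idempotent, warns when empty", {
  days <- as.Date("2021-01-11") + 0:34
  tab <- tidyr::expand_grid(cage_id = c("C01", "C02"), day = days) |>
    dplyr::mutate(value = 1)
  md <- tibble::tibble(
    cage_id = c("C01", "C02"),
    cage_change_dates = list(days[c(1, 8, 15, 22, 29)], days[c(1, 8, 15, 22, 29)])
  )
  out <- suppressMessages(exclude_days(tab, md))
  expect_equal(nrow(out), 2 * 30) # 35 days minus 5 weekly changes
  expect_identical(suppressMessages(exclude_days(out, md)), out)

  # no change dates: identity
  md0 <- tibble::tibble(cage_id = c("C01", "C02"),
                        cage_change_dates = list(as.Date(character()), as.Date(character())))
  expect_identical(exclude_days(tab, md0), tab)

  # everything excluded: empty with a warning
  md_all <- tibble::tibble(cage_id = c("C01", "C02"),
                           cage_change_dates = list(days, days))
  expect_warning(suppressMessages(exclude_days(tab, md_all)), "empty")
})

test_that("weekly aggregation equals brute-force per-week means", {
  set.seed(7)
  days <- as.Date("2021-01-11") + 0:27
  tab <- tidyr::expand_grid(
    cage_id = c("C01", "C02"), day = days,
    phase = factor(c("light", "dark"), levels = c("light", "dark")),
    metric = c("m1", "m2")
  ) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  wk <- weekly_aggregate(tab)
  # brute force over every cell
  for (k in sample(nrow(wk), 20)) {
    row <- wk[k, ]
    sel <- tab$cage_id == row$cage_id & tab$phase == row$phase &
      tab$metric == row$metric &
      as.integer(tab$day - min(tab$day)) %/% 7 + 1 == row$week
    expect_equal(row$value, mean(tab$value[sel]))
  }
  expect_true(all(wk$n_days == 7))
  # constant values aggregate to the constant
  tab2 <- dplyr::mutate(tab, value = 2)
  expect_true(all(weekly_aggregate(tab2)$value == 2))
})
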