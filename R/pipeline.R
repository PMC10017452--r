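#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cage rest/activity metric extraction
#'
#' Computes, for one or more cages, the full metric battery consumed by the
#' statistics stage: per day x phase mean activity, RDI and percent zero
#' activity; percent zero per hour post lights-on; the least active hour; and
#' rest bouts.
#'
#' @param activity Tibble `timestamp, cage_id, activity` (1-min resolution).
#' @param immobility Tibble `timestamp, cage_id, immobile` (1-s resolution),
#'   or NULL to skip immobility-based metrics.
#' @param schedule A [light_schedule()].
#' @param config An [analysis_config()].
#' @return List of tibbles `daily` (long: cage_id, day, phase, metric,
#'   value), `hourly`, `lah`, `bouts`.
#' @export
analyze_cages <- function(activity, immobility = NULL,
                          schedule = light_schedule(),
                          config = analysis_config()) {
  act_daily <- assign_phases(activity, schedule) |>
    dplyr::group_by(.data$cage_id, .data$day, .data$phase) |>
    dplyr::summarise(value = mean(.data$activity, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(metric = "activity_mean")
  rdi <- compute_rdi(activity, schedule, config) |>
    dplyr::transmute(.data$cage_id, .data$day, .data$phase,
                     metric = "rdi", value = .data$rdi)
  daily <- dplyr::bind_rows(act_daily, rdi)
  hourly <- NULL; lah <- NULL; bouts <- NULL
  if (!is.null(immobility)) {
    hourly <- percent_zero_per_hour(immobility, schedule)
    pz_daily <- hourly |>
      dplyr::group_by(.data$cage_id, .data$day, .data$phase) |>
      dplyr::summarise(
        value = sum(.data$pct_zero * .data$n_seconds) / sum(.data$n_seconds),
        .groups = "drop"
      ) |>
      dplyr::mutate(metric = "pct_zero")
    daily <- dplyr::bind_rows(daily, pz_daily)
    bouts <- detect_rest_bouts(immobility, config$bout_min, schedule)
  }
  lah <- least_active_hour(activity, schedule)
  list(
    daily = dplyr::arrange(daily, .data$cage_id, .data$day, .data$phase, .data$metric),
    hourly = hourly, lah = lah, bouts = bouts
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates activation-derived series through metrics, exclusion of
#' cage-change days, weekly aggregation, bout histograms and the rank-based
#' statistics, optionally writing a deterministic CSV bundle. Stages run in a
#' fixed order and all outputs are sorted, so re-running on identical inputs
#' reproduces byte-identical files.
#'
#' @param cohort Either the list returned by [simulate_cohort()] or a list
#'   with elements `activity`, `immobility` (optional) and `metadata`
#'   (tibbles in the package's interchange layouts).
#' @param config An [analysis_config()].
#' @param schedule A [light_schedule()].
#' @param out_dir Output directory for the CSV bundle, or NULL to skip
#'   writing.
#' @return List with `daily`, `hourly`, `lah`, `bouts`, `weekly`,
#'   `bout_hist`, `long_bouts`, `lah_dark`, `stats`, `posthoc` tibbles.
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         schedule = light_schedule(), out_dir = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$activity), !is.null(cohort$metadata))
  metrics <- analyze_cages(cohort$activity, cohort$immobility, schedule, config)
  summarize_pipeline(metrics, cohort$metadata, config, out_dir = out_dir)
}

#' Simulate and analyze a cohort cage by cage
#'
#' Streaming variant of [simulate_cohort()] + [run_pipeline()] that never
#' materializes the cohort's full per-second table: each cage is simulated,
#' reduced to its metric tables and discarded. Intended for study-scale
#' cohorts (tens of cages over several weeks).
#'
#' @inheritParams simulate_cohort
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for the CSV bundle.
#' @return As [run_pipeline()], plus `ground_truth`.
#' @export
simulate_and_analyze <- function(params = simulation_params(), seed = 1,
                                 config = analysis_config(), out_dir = NULL) {
  layout <- cohort_layout(params, as.integer(seed))
  pieces <- purrr::pmap(layout, function(cage_id, sex, genotype, cage_seed) {
    s <- simulate_cage(params, sex, genotype, cage_id, cage_seed)
    m <- analyze_cages(s$activity, s$immobility, params$schedule, config)
    m$truth <- s$ground_truth
    m
  })
  metrics <- list(
    daily = purrr::map_dfr(pieces, "daily"),
    hourly = purrr::map_dfr(pieces, "hourly"),
    lah = purrr::map_dfr(pieces, "lah"),
    bouts = purrr::map_dfr(pieces, "bouts")
  )
  start_day <- as.Date(params$start)
  change_days <- seq(start_day, by = params$cage_change_every,
                     length.out = ceiling(params$weeks * 7 / params$cage_change_every))
  metadata <- layout |>
    dplyr::mutate(n_animals = 2L, cohort = "SIM1",
                  cage_change_dates = rep(list(change_days), dplyr::n())) |>
    dplyr::select("cage_id", "genotype", "sex", "n_animals", "cohort",
                  "cage_change_dates")
  out <- summarize_pipeline(metrics, metadata, config, out_dir = out_dir)
  out$ground_truth <- purrr::map_dfr(pieces, function(p) {
    tt <- p$truth
    tibble::tibble(
      cage_id = tt$cage_id, sex = tt$sex, genotype = tt$genotype,
      phase = factor(c("light", "dark"), levels = c("light", "dark")),
      target_rest_frac = unname(tt$target_rest_frac),
      realized_rest_frac = unname(tt$realized_rest_frac)
    )
  })
  out
}

summarize_pipeline <- function(metrics, metadata, config, out_dir = NULL) {
  md <- dplyr::select(metadata, "cage_id", "sex", "genotype")
  start_day <- min(metrics$daily$day)

  daily <- exclude_days(metrics$daily, metadata, quiet = TRUE)
  hourly <- if (!is.null(metrics$hourly)) exclude_days(metrics$hourly, metadata, quiet = TRUE)
  lah <- if (!is.null(metrics$lah)) exclude_days(metrics$lah, metadata, quiet = TRUE)
  bouts <- if (!is.null(metrics$bouts)) exclude_days(metrics$bouts, metadata, quiet = TRUE)

  weekly <- weekly_aggregate(daily, start_day = start_day)

  bout_hist <- NULL; long_bouts <- NULL
  if (!is.null(bouts) && nrow(bouts) > 0) {
    bout_hist <- time_weighted_histogram(
      dplyr::group_by(bouts, .data$cage_id),
      bins = config$bout_bins, bout_min = config$bout_min
    )
    long_bouts <- long_bout_fraction(
      dplyr::group_by(bouts, .data$cage_id),
      threshold = config$long_bout_threshold
    )
  }
  lah_dark <- NULL
  if (!is.null(lah) && nrow(lah) > 0) {
    lah_dark <- lah |>
      dplyr::left_join(md, by = "cage_id") |>
      dplyr::group_by(.data$sex, .data$genotype) |>
      lah_dark_fraction()
  }

  stats_tbl <- pipeline_ats(weekly, md)
  posthoc <- pipeline_posthoc(hourly, bout_hist, md, config)

  out <- list(
    daily = daily, hourly = hourly, lah = lah, bouts = bouts,
    weekly = weekly, bout_hist = bout_hist, long_bouts = long_bouts,
    lah_dark = lah_dark, stats = stats_tbl, posthoc = posthoc,
    config = config
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, metadata, out_dir)
  out
}

# ANOVA-type tests per metric x phase on weekly cage means
pipeline_ats <- function(weekly, md) {
  combos <- weekly |>
    dplyr::distinct(.data$metric, .data$phase)
  purrr::pmap_dfr(combos, function(metric, phase) {
    d <- weekly[weekly$metric == metric & weekly$phase == phase, ]
    d <- dplyr::left_join(d, md, by = "cage_id")
    # drop weeks not observed for every cage (e.g. fully excluded)
    ok_weeks <- d |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::count(.data$week) |>
      dplyr::filter(.data$n == dplyr::n_distinct(d$cage_id))
    d <- d[d$week %in% ok_weeks$week & !is.na(d$value), ]
    if (dplyr::n_distinct(d$week) < 1) return(tibble::tibble())
    fit <- ats_f2_ld_f1(d)
    dplyr::mutate(tidy(fit), metric = metric, phase = phase,
                  .before = 1)
  })
}

# Wilcoxon post-hocs: mutant vs wild-type within sex, Bonferroni per family
pipeline_posthoc <- function(hourly, bout_hist, md, config) {
  res <- list()
  if (!is.null(hourly)) {
    per_cage <- hourly |>
      dplyr::group_by(.data$cage_id, .data$hour, .data$phase) |>
      dplyr::summarise(value = mean(.data$pct_zero, na.rm = TRUE), .groups = "drop") |>
      dplyr::left_join(md, by = "cage_id")
    res$pct_zero <- per_cage |>
      dplyr::group_by(.data$sex, .data$hour, .data$phase) |>
      dplyr::group_modify(function(d, key) {
        wilcox_cell(d$value[d$genotype == "MUT"], d$value[d$genotype == "WT"])
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$sex) |>
      dplyr::mutate(p_adj = bonferroni(.data$p_value, m = 24L),
                    metric = "pct_zero_hourly") |>
      dplyr::ungroup()
  }
  if (!is.null(bout_hist)) {
    n_bins <- dplyr::n_distinct(bout_hist$bin)
    per_cage <- dplyr::left_join(bout_hist, md, by = "cage_id")
    res$bouts <- per_cage |>
      dplyr::group_by(.data$sex, .data$phase, .data$bin) |>
      dplyr::group_modify(function(d, key) {
        wilcox_cell(d$weight[d$genotype == "MUT"], d$weight[d$genotype == "WT"])
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$sex, .data$phase) |>
      dplyr::mutate(p_adj = bonferroni(.data$p_value, m = n_bins),
                    metric = "bout_weight") |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(res)
}

wilcox_cell <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          method = NA_character_))
  }
  suppressWarnings(wilcoxon_two_sample(x, y))
}

write_pipeline_outputs <- function(out, metadata, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (is.null(x) || nrow(x) == 0) return(invisible(NULL))
    for (nm in names(x)) {
      if (inherits(x[[nm]], "POSIXct")) {
        x[[nm]] <- format(x[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    readr::write_csv(x, file.path(out_dir, name))
  }
  wr(out$daily, "metrics_daily.csv")
  wr(out$hourly, "pct_zero_hourly.csv")
  wr(out$lah, "least_active_hour.csv")
  wr(out$bouts, "bouts.csv")
  wr(out$weekly, "metrics_weekly.csv")
  wr(out$bout_hist, "bout_histogram.csv")
  wr(out$long_bouts, "long_bouts.csv")
  wr(out$lah_dark, "lah_dark_fraction.csv")
  wr(out$stats, "stats.csv")
  wr(out$posthoc, "posthoc.csv")
  write_cage_metadata(metadata, file.path(out_dir, "metadata.csv"))
  cfg <- out$config
  writeLines(
    c(
      "cagerest pipeline run",
      sprintf("config_hash: %s", rlang::hash(unclass(cfg))),
      sprintf("%s: %s", names(unclass(cfg)),
              vapply(unclass(cfg), \(v) paste(format(v), collapse = ","), character(1)))
    ),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}
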