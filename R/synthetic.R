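#' Simulation parameters for a synthetic home-cage cohort
#'
#' Full generative specification of a study cohort monitored in capacitance
#' home cages: per (sex x genotype) cage counts, recording length, photoperiod,
#' two-state (REST/ACTIVE) semi-Markov dynamics with log-normal dwell times
#' per phase, circadian modulation, emission of per-minute activity, and
#' multiplicative group effects. Defaults emulate a 5-week study of a
#' dystrophic mutant line and wild-type littermates housed two per cage
#' (10 + 10 male and 11 + 8 female cages), nocturnal controls with higher
#' female activity, and a mutant phenotype of reduced activity plus doubled
#' dark-phase rest dwell times (longer rest bouts in the active phase).
#'
#' The per-phase stationary rest fraction implied by the dwell parameters is
#' `rest_frac`; active dwell means are derived from the rest dwell means so
#' the renewal-theory fraction `E[rest] / (E[rest] + E[active])` hits the
#' target. The mutant dark rest-dwell multiplier raises both the dark rest
#' fraction and the share of long bouts.
#'
#' @param n_cages Named integer vector of cages per group, names
#'   `M_WT, M_MUT, F_WT, F_MUT`.
#' @param weeks Recording length in weeks (default 5).
#' @param start Recording start (a lights-on instant, POSIXct UTC).
#' @param schedule A [light_schedule()].
#' @param rest_frac Target stationary rest fraction per phase in controls,
#'   named `light`, `dark`.
#' @param dwell_rest_median Median rest-bout dwell per phase, seconds.
#' @param dwell_rest_sdlog,dwell_active_sdlog Log-normal shape parameters.
#' @param activity_level Mean per-minute activity index of a fully active
#'   minute in control males (0-1 scale).
#' @param genotype_rest_dwell_mult Multiplier on the mutant dark-phase rest
#'   dwell mean (default 2).
#' @param genotype_activity_mult Multiplier on mutant activity level
#'   (default 0.7).
#' @param sex_activity_mult Multiplier on female activity level (default 1.3).
#' @param circadian_profile 24 hourly multipliers on ACTIVE dwell propensity
#'   (hour 0 = lights-on; default flat, the light/dark dichotomy already
#'   carries the circadian structure).
#' @param noise_sd SD of the multiplicative emission noise on active-minute
#'   activity.
#' @param cage_change_every Cage-change interval in days (default 7; changes
#'   fall on recording days 1, 8, 15, ...).
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(n_cages = c(M_WT = 10L, M_MUT = 10L, F_WT = 11L, F_MUT = 8L),
                              weeks = 5,
                              start = as.POSIXct("2021-01-11 07:00:00", tz = "UTC"),
                              schedule = light_schedule(),
                              rest_frac = c(light = 0.65, dark = 0.35),
                              dwell_rest_median = c(light = 90, dark = 60),
                              dwell_rest_sdlog = c(light = 1.0, dark = 0.9),
                              dwell_active_sdlog = c(light = 1.0, dark = 1.0),
                              activity_level = 0.25,
                              genotype_rest_dwell_mult = 2,
                              genotype_activity_mult = 0.7,
                              sex_activity_mult = 1.3,
                              circadian_profile = rep(1, 24),
                              noise_sd = 0.12,
                              cage_change_every = 7) {
  stopifnot(
    all(c("M_WT", "M_MUT", "F_WT", "F_MUT") %in% names(n_cages)),
    weeks > 0, all(rest_frac > 0 & rest_frac < 1),
    all(dwell_rest_median > 0), all(dwell_rest_sdlog > 0),
    genotype_rest_dwell_mult > 0, genotype_activity_mult > 0,
    sex_activity_mult > 0, length(circadian_profile) == 24,
    all(circadian_profile > 0), noise_sd >= 0,
    activity_level > 0, activity_level <= 1
  )
  meanlog_rest <- log(dwell_rest_median)
  mean_rest <- exp(meanlog_rest + dwell_rest_sdlog^2 / 2)
  mean_active <- mean_rest * (1 - rest_frac) / rest_frac
  meanlog_active <- log(mean_active) - dwell_active_sdlog^2 / 2
  structure(
    list(
      n_cages = n_cages, weeks = weeks, start = start, schedule = schedule,
      rest_frac = rest_frac,
      meanlog_rest = meanlog_rest, sdlog_rest = dwell_rest_sdlog,
      meanlog_active = meanlog_active, sdlog_active = dwell_active_sdlog,
      mean_rest = mean_rest, mean_active = mean_active,
      activity_level = activity_level,
      genotype_rest_dwell_mult = genotype_rest_dwell_mult,
      genotype_activity_mult = genotype_activity_mult,
      sex_activity_mult = sex_activity_mult,
      circadian_profile = circadian_profile,
      noise_sd = noise_sd, cage_change_every = cage_change_every
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %s cages, %g weeks; rest fraction light %.2f / dark %.2f\n",
    paste(sprintf("%s=%d", names(x$n_cages), x$n_cages), collapse = " "),
    x$weeks, x$rest_frac[["light"]], x$rest_frac[["dark"]]
  ))
  cat(sprintf(
    "  mutant: dark rest dwell x%g, activity x%g; female activity x%g\n",
    x$genotype_rest_dwell_mult, x$genotype_activity_mult, x$sex_activity_mult
  ))
  invisible(x)
}

#' Simulate one cage
#'
#' Runs the two-state semi-Markov model for one cage: alternating REST and
#' ACTIVE dwells drawn from phase-specific log-normals (the phase and hour at
#' each dwell's onset select its parameters; dwells may straddle phase
#' boundaries), expanded to a per-second immobility series (REST = 1) and a
#' per-minute activity series (activity = fraction of the minute spent
#' ACTIVE, times the group activity level and hourly circadian multiplier,
#' with multiplicative Gaussian noise, clipped to `[0, 1]`). Output is fully
#' determined by `seed`.
#'
#' @param params A [simulation_params()] object.
#' @param sex `"M"` or `"F"`.
#' @param genotype `"WT"` or `"MUT"`.
#' @param cage_id Cage identifier string.
#' @param seed Integer seed for this cage.
#' @return List with `activity` and `immobility` tibbles and a `ground_truth`
#'   list (realized per-phase rest fractions and targets, realized rest-dwell
#'   durations, group emission parameters).
#' @export
simulate_cage <- function(params, sex, genotype, cage_id, seed) {
  stopifnot(inherits(params, "sim_params"), sex %in% c("M", "F"),
            genotype %in% c("WT", "MUT"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  n_sec <- round(params$weeks * 7 * 86400)
  sch <- params$schedule
  start_num <- as.numeric(params$start)
  rest_mult <- c(light = 1, dark = if (genotype == "MUT") params$genotype_rest_dwell_mult else 1)
  level <- params$activity_level *
    (if (genotype == "MUT") params$genotype_activity_mult else 1) *
    (if (sex == "F") params$sex_activity_mult else 1)

  # alternate dwell draws; parameters chosen by phase/hour at dwell onset
  cap <- ceiling(n_sec / min(params$mean_rest, params$mean_active)) + 1000L
  states <- integer(cap); durs <- numeric(cap)
  zpool <- rnorm(cap) # pre-drawn dwell innovations
  t_cur <- 0; k <- 0L
  p_rest0 <- params$rest_frac[["light"]]
  state <- if (runif(1) < p_rest0) 1L else 0L # 1 = REST
  while (t_cur < n_sec) {
    tod <- (start_num + t_cur) %% 86400
    in_light <- if (sch$on_sec < sch$off_sec) {
      tod >= sch$on_sec && tod < sch$off_sec
    } else tod >= sch$on_sec || tod < sch$off_sec
    ph <- if (in_light) "light" else "dark"
    hr <- as.integer(((tod - sch$on_sec) %% 86400) %/% 3600) + 1L
    k <- k + 1L
    if (k > length(states)) { # rare overflow
      states <- c(states, integer(cap)); durs <- c(durs, numeric(cap))
      zpool <- c(zpool, rnorm(cap))
    }
    dur <- if (state == 1L) {
      exp(params$meanlog_rest[[ph]] + log(rest_mult[[ph]]) +
            params$sdlog_rest[[ph]] * zpool[k])
    } else {
      exp(params$meanlog_active[[ph]] + log(params$circadian_profile[hr]) +
            params$sdlog_active[[ph]] * zpool[k])
    }
    dur <- max(1, round(dur))
    states[k] <- state
    durs[k] <- dur
    t_cur <- t_cur + dur
    state <- 1L - state
  }
  states <- states[seq_len(k)]; durs <- durs[seq_len(k)]
  imm <- rep(states, durs)[seq_len(n_sec)]

  # per-minute activity emission
  n_min <- n_sec %/% 60
  min_idx <- rep(seq_len(n_min), each = 60)
  active_sec <- tabulate(min_idx[imm[seq_len(n_min * 60)] == 0L], nbins = n_min)
  frac_active <- active_sec / 60
  min_start <- start_num + (seq_len(n_min) - 1) * 60
  hr_min <- as.integer((((min_start %% 86400) - sch$on_sec) %% 86400) %/% 3600) + 1L
  act <- frac_active * level * params$circadian_profile[hr_min]
  act <- act * pmax(0, 1 + rnorm(n_min, 0, params$noise_sd))
  act <- pmin(1, pmax(0, act))

  sec_ts <- as.POSIXct(start_num + seq_len(n_sec) - 1, origin = "1970-01-01", tz = "UTC")
  tod_sec <- (start_num + seq_len(n_sec) - 1) %% 86400
  sec_light <- if (sch$on_sec < sch$off_sec) {
    tod_sec >= sch$on_sec & tod_sec < sch$off_sec
  } else tod_sec >= sch$on_sec | tod_sec < sch$off_sec

  truth <- list(
    cage_id = cage_id, sex = sex, genotype = genotype,
    target_rest_frac = c(
      light = unname(params$rest_frac[["light"]]),
      dark = stationary_rest_frac(params, "dark", genotype)
    ),
    realized_rest_frac = c(
      light = mean(imm[sec_light]),
      dark = mean(imm[!sec_light])
    ),
    rest_dwells = durs[states == 1L],
    activity_level = level
  )
  list(
    activity = tibble::tibble(
      timestamp = as.POSIXct(min_start, origin = "1970-01-01", tz = "UTC"),
      cage_id = cage_id, activity = act
    ),
    immobility = tibble::tibble(
      timestamp = sec_ts, cage_id = cage_id, immobile = as.integer(imm)
    ),
    ground_truth = truth
  )
}

# renewal-theory stationary rest fraction for a phase/genotype
stationary_rest_frac <- function(params, phase, genotype) {
  mult <- if (genotype == "MUT" && phase == "dark") params$genotype_rest_dwell_mult else 1
  mr <- params$mean_rest[[phase]] * mult
  unname(mr / (mr + params$mean_active[[phase]]))
}

#' Simulate a full cohort
#'
#' Draws every cage of the study layout (one seed per cage, derived
#' deterministically from `seed`), assembles the per-minute activity table,
#' optionally the per-second immobility table, cage metadata with weekly
#' cage-change dates, and the ground-truth bundle for parameter-recovery
#' tests.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer master seed.
#' @param include_immobility Keep the (large) per-second table (default TRUE).
#' @return List `activity`, `immobility` (or NULL), `metadata`,
#'   `ground_truth` (tibble of realized vs target rest fractions per cage),
#'   `bouts_true` (list of realized rest-dwell vectors).
#' @export
simulate_cohort <- function(params = simulation_params(), seed = 1,
                            include_immobility = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  layout <- cohort_layout(params, as.integer(seed))
  sims <- purrr::pmap(layout, function(cage_id, sex, genotype, cage_seed) {
    simulate_cage(params, sex, genotype, cage_id, cage_seed)
  })
  truth <- purrr::map_dfr(sims, function(s) {
    tt <- s$ground_truth
    tibble::tibble(
      cage_id = tt$cage_id, sex = tt$sex, genotype = tt$genotype,
      phase = factor(c("light", "dark"), levels = c("light", "dark")),
      target_rest_frac = unname(tt$target_rest_frac),
      realized_rest_frac = unname(tt$realized_rest_frac),
      activity_level = tt$activity_level
    )
  })
  start_day <- as.Date(params$start)
  change_days <- seq(start_day, by = params$cage_change_every,
                     length.out = ceiling(params$weeks * 7 / params$cage_change_every))
  metadata <- layout |>
    dplyr::mutate(
      n_animals = 2L, cohort = "SIM1",
      cage_change_dates = rep(list(change_days), dplyr::n())
    ) |>
    dplyr::select("cage_id", "genotype", "sex", "n_animals", "cohort",
                  "cage_change_dates")
  list(
    activity = purrr::map_dfr(sims, "activity"),
    immobility = if (include_immobility) purrr::map_dfr(sims, "immobility") else NULL,
    metadata = metadata,
    ground_truth = truth,
    bouts_true = purrr::map(sims, function(s) s$ground_truth$rest_dwells),
    params = params, seed = seed
  )
}

# cage layout with per-cage seeds; seeds stay well below 2^31
cohort_layout <- function(params, seed) {
  if (missing(seed)) seed <- 1L
  groups <- c("M_WT", "M_MUT", "F_WT", "F_MUT")
  n <- params$n_cages[groups]
  tibble::tibble(
    group = rep(groups, n),
    idx = seq_len(sum(n))
  ) |>
    tidyr::separate_wider_delim("group", "_", names = c("sex", "genotype")) |>
    dplyr::mutate(
      cage_id = sprintf("C%02d", .data$idx),
      cage_seed = as.integer((as.numeric(seed) * 1000 + .data$idx) %% 2147483647)
    ) |>
    dplyr::select("cage_id", "sex", "genotype", "cage_seed")
}
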