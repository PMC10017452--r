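#' Activity heatmap (minutes x days)
#'
#' Raster of per-minute activity with one row per lights-on-anchored day and
#' one column per minute post lights-on; several cages are averaged per cell.
#' The dark band of the photoperiod is annotated. The underlying matrix is
#' the plot's `$data` (no resampling), so figures can be checked numerically.
#'
#' @param activity Tibble `timestamp, cage_id, activity` (1-min resolution).
#' @param schedule A [light_schedule()].
#' @return A ggplot object.
#' @export
plot_activity_heatmap <- function(activity, schedule = light_schedule()) {
  d <- assign_phases(activity, schedule) |>
    dplyr::mutate(
      minute = as.integer(((as.numeric(.data$timestamp) - schedule$on_sec) %% 86400) %/% 60)
    ) |>
    dplyr::group_by(.data$day, .data$minute) |>
    dplyr::summarise(activity = mean(.data$activity, na.rm = TRUE), .groups = "drop")
  dark_start <- schedule$light_hours * 60
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute, y = .data$day, fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = dark_start, linetype = 2, colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "minute post lights-on", y = "day", fill = "activity") +
    ggplot2::theme_minimal()
}

#' Weekly phase summary bars
#'
#' Group mean with SEM error bars of a weekly metric (e.g. mean activity or
#' RDI) per week, split by light/dark phase and coloured by sex x genotype
#' group.
#'
#' @param weekly Output of [weekly_aggregate()].
#' @param metadata Cage metadata (for sex/genotype).
#' @param metric Which metric to plot.
#' @return A ggplot object.
#' @export
plot_phase_summary <- function(weekly, metadata, metric = "activity_mean") {
  d <- weekly |>
    dplyr::filter(.data$metric == !!metric, !is.na(.data$value)) |>
    dplyr::left_join(dplyr::select(metadata, "cage_id", "sex", "genotype"),
                     by = "cage_id") |>
    dplyr::group_by(.data$week, .data$phase, .data$sex, .data$genotype) |>
    dplyr::summarise(
      mean = mean(.data$value), sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = paste(.data$sex, .data$genotype))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$week), y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "week", y = metric) +
    ggplot2::theme_minimal()
}

#' Hourly percent-zero-activity profile
#'
#' Group mean with SEM of the percentage of zero-activity time per hour post
#' lights-on.
#'
#' @param hourly Output of [percent_zero_per_hour()].
#' @param metadata Cage metadata.
#' @return A ggplot object.
#' @export
plot_percent_zero <- function(hourly, metadata) {
  d <- hourly |>
    dplyr::left_join(dplyr::select(metadata, "cage_id", "sex", "genotype"),
                     by = "cage_id") |>
    dplyr::group_by(.data$cage_id, .data$sex, .data$genotype, .data$hour) |>
    dplyr::summarise(pct = mean(.data$pct_zero, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$sex, .data$genotype, .data$hour) |>
    dplyr::summarise(
      mean = mean(.data$pct), sem = stats::sd(.data$pct) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = paste(.data$sex, .data$genotype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hour, y = .data$mean,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::geom_vline(xintercept = 12.5, linetype = 2) +
    ggplot2::labs(x = "hour post lights-on", y = "% time zero activity") +
    ggplot2::theme_minimal()
}

#' Least-active-hour start-time histogram
#'
#' Distribution of the daily least-active-hour start time (minutes post
#' lights-on), faceted by sex x genotype; the dark phase begins at the dashed
#' line.
#'
#' @param lah Output of [least_active_hour()].
#' @param metadata Cage metadata.
#' @param schedule A [light_schedule()].
#' @return A ggplot object.
#' @export
plot_lah_histogram <- function(lah, metadata, schedule = light_schedule()) {
  d <- lah |>
    dplyr::left_join(dplyr::select(metadata, "cage_id", "sex", "genotype"),
                     by = "cage_id") |>
    dplyr::mutate(group = paste(.data$sex, .data$genotype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start_minute / 60)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0, fill = "grey40") +
    ggplot2::geom_vline(xintercept = schedule$light_hours, linetype = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "least active hour start (h post lights-on)", y = "days") +
    ggplot2::theme_minimal()
}

#' Time-weighted rest-bout histogram plot
#'
#' Group mean bout-bin weights per phase (weights of each duration bin in
#' total rest time).
#'
#' @param bout_hist Per-cage output of [time_weighted_histogram()].
#' @param metadata Cage metadata.
#' @return A ggplot object.
#' @export
plot_bout_histogram <- function(bout_hist, metadata) {
  d <- bout_hist |>
    dplyr::left_join(dplyr::select(metadata, "cage_id", "sex", "genotype"),
                     by = "cage_id") |>
    dplyr::group_by(.data$sex, .data$genotype, .data$phase, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$weight), sem = stats::sd(.data$weight) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = paste(.data$sex, .data$genotype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "bout duration bin", y = "time-weighted share of rest") +
    ggplot2::theme_minimal()
}
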