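#' Label samples with light/dark phase and lights-on-anchored day
#'
#' Adds three columns to any table carrying a `timestamp` column (POSIXct,
#' UTC): `phase` (`"light"`/`"dark"`, half-open `[lights_on, lights_off)`),
#' `day` (the calendar date of the lights-on instant that starts the 24-h
#' analysis day the sample falls in), and `hour` (0-23, whole hours elapsed
#' since that lights-on). Anchoring days at lights-on keeps both 12-h phases
#' of one behavioural day together, which is what hourly "post lights-on"
#' summaries assume.
#'
#' @param data A data frame with a POSIXct `timestamp` column.
#' @param schedule A [light_schedule()].
#' @return The input as a tibble with `phase`, `day` and `hour` columns.
#' @examples
#' x <- tibble::tibble(
#'   timestamp = as.POSIXct("2021-01-11 07:00:00", tz = "UTC") + c(0, 3600 * 12)
#' )
#' assign_phases(x, light_schedule())
#' @export
assign_phases <- function(data, schedule = light_schedule()) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (!"timestamp" %in% names(data)) stop("data needs a 'timestamp' column", call. = FALSE)
  ts <- as.numeric(data$timestamp)
  tod <- ts %% 86400
  on <- schedule$on_sec
  off <- schedule$off_sec
  in_light <- if (on < off) tod >= on & tod < off else tod >= on | tod < off
  anchor_day <- (ts - on) %/% 86400
  out <- dplyr::as_tibble(data)
  out$phase <- structure(2L - in_light, levels = c("light", "dark"), class = "factor")
  out$day <- as.Date(anchor_day, origin = "1970-01-01")
  out$hour <- as.integer(((tod - on) %% 86400) %/% 3600)
  out
}

#' Drop cage-change days from a metric table
#'
#' Husbandry days (cage changes) disturb home-cage behaviour and are excluded
#' from analysis. Removes every row whose lights-on-anchored `day` is listed in
#' the cage's `cage_change_dates`. Idempotent.
#'
#' @param data A table with `cage_id` and `day` (Date) columns.
#' @param metadata Cage metadata with `cage_id` and `cage_change_dates`
#'   (list-column of Dates, or semicolon-separated date strings).
#' @param quiet Suppress the per-cage removal message.
#' @return Filtered tibble.
#' @export
exclude_days <- function(data, metadata, quiet = FALSE) {
  stopifnot(all(c("cage_id", "day") %in% names(data)))
  data <- dplyr::as_tibble(data)
  changes <- normalize_change_dates(metadata)
  if (nrow(changes) == 0) return(data)
  keep <- !paste(data$cage_id, data$day) %in% paste(changes$cage_id, changes$day)
  removed <- data[!keep, , drop = FALSE]
  if (!quiet && nrow(removed) > 0) {
    tally <- dplyr::count(removed, .data$cage_id)
    message(
      "exclude_days: removed ",
      paste(sprintf("%d row(s) [%s]", tally$n, tally$cage_id), collapse = ", ")
    )
  }
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("all days excluded; empty table returned", call. = FALSE)
  out
}

# metadata cage_change_dates -> tibble(cage_id, day)
normalize_change_dates <- function(metadata) {
  stopifnot("cage_id" %in% names(metadata))
  cc <- metadata[["cage_change_dates"]]
  if (is.null(cc)) return(tibble::tibble(cage_id = character(), day = as.Date(character())))
  if (!is.list(cc)) cc <- strsplit(as.character(cc), ";", fixed = TRUE)
  out <- tibble::tibble(cage_id = rep(metadata$cage_id, lengths(cc)),
                        day = as.Date(unlist(lapply(cc, as.character)), format = "%Y-%m-%d"))
  out[!is.na(out$day), , drop = FALSE]
}

#' Aggregate per-day metrics into per-cage weekly means
#'
#' Week 1 is the first seven recording days (counted from `start_day`, by
#' default the earliest day in the table), so weekly means line up across
#' cages recorded in the same cohort window. Weeks in the observed range with
#' no contributing days (e.g. fully excluded) are kept as `NA` and flagged.
#'
#' @param data Long metric table with columns `cage_id`, `day`, `phase`,
#'   `metric`, `value` (extra columns are ignored).
#' @param start_day Date anchoring week 1; default `min(data$day)`.
#' @return Tibble `cage_id, week, phase, metric, value, n_days, flag`.
#' @export
weekly_aggregate <- function(data, start_day = NULL) {
  stopifnot(all(c("cage_id", "day", "phase", "metric", "value") %in% names(data)))
  if (nrow(data) == 0) {
    return(tibble::tibble(
      cage_id = character(), week = integer(), phase = factor(levels = c("light", "dark")),
      metric = character(), value = double(), n_days = integer(), flag = character()
    ))
  }
  if (is.null(start_day)) start_day <- min(data$day)
  out <- data |>
    dplyr::mutate(week = as.integer((as.integer(.data$day - as.Date(start_day))) %/% 7L) + 1L) |>
    dplyr::group_by(.data$cage_id, .data$week, .data$phase, .data$metric) |>
    dplyr::summarise(
      n_days = sum(!is.na(.data$value)),
      value = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::complete(
      .data$cage_id, .data$week, .data$phase, .data$metric,
      fill = list(value = NA_real_, n_days = 0L)
    ) |>
    dplyr::mutate(
      value = ifelse(is.nan(.data$value), NA_real_, .data$value),
      flag = ifelse(.data$n_days == 0L | is.na(.data$value), "no_days", "ok")
    ) |>
    dplyr::arrange(.data$cage_id, .data$week, .data$phase, .data$metric)
  out
}
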