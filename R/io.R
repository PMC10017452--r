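#' Read a raw capacitance table
#'
#' Expects the long interchange layout `timestamp, cage_id, e01..e12` with
#' ISO-8601 timestamps and exactly 12 electrode columns. Timestamps must be
#' strictly increasing within each cage. Sampling gaps are regularized: the
#' record is expanded onto the full `1/fs`-second grid from first to last
#' sample per cage, with missing slots carried as `NA` electrode rows (masked
#' samples) so downstream metrics can renormalize their denominators instead
#' of fabricating rest.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @return Tibble `timestamp, cage_id, e01..e12` with attribute `fs`;
#'   masked (gap) samples have `NA` in all electrode columns.
#' @export
read_capacitance_csv <- function(path, fs = 4) {
  stopifnot(file.exists(path), fs > 0)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  ecols <- grep("^e[0-9]{2}$", names(raw), value = TRUE)
  if (length(ecols) != 12) {
    stop(sprintf("capacitance format error: expected 12 electrode columns e01..e12, found %d",
                 length(ecols)), call. = FALSE)
  }
  if (!all(c("timestamp", "cage_id") %in% names(raw))) {
    stop("capacitance format error: need 'timestamp' and 'cage_id' columns", call. = FALSE)
  }
  if (!inherits(raw$timestamp, "POSIXct")) {
    raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC")
  }
  attr(raw$timestamp, "tzone") <- "UTC"
  step <- 1 / fs
  out <- raw |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::group_modify(function(d, key) {
      tnum <- as.numeric(d$timestamp)
      if (is.unsorted(tnum, strictly = TRUE)) {
        stop(sprintf("capacitance data error: non-monotone timestamps in cage %s",
                     key$cage_id[[1]]), call. = FALSE)
      }
      # snap to the sampling grid anchored at the first sample
      idx <- as.integer(round((tnum - tnum[1]) / step))
      grid <- tibble::tibble(.slot = seq.int(0L, idx[length(idx)]))
      d$.slot <- idx
      full <- dplyr::left_join(grid, d, by = ".slot")
      full$timestamp <- as.POSIXct(tnum[1] + full$.slot * step,
                                   origin = "1970-01-01", tz = "UTC")
      dplyr::select(full, -".slot")
    }) |>
    dplyr::ungroup() |>
    dplyr::select("timestamp", "cage_id", dplyr::all_of(sort(ecols)))
  attr(out, "fs") <- fs
  out
}

#' @rdname read_capacitance_csv
#' @param data Capacitance tibble as returned by [read_capacitance_csv()] or
#'   [emit_capacitance()].
#' @export
write_capacitance_csv <- function(data, path) {
  data$timestamp <- format(data$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  readr::write_csv(data, path)
  invisible(path)
}

#' Read/write per-minute activity and per-second immobility tables
#'
#' The interchange layouts are `timestamp, cage_id, activity` (one row per
#' minute, activity in `[0, 1]`) and `timestamp, cage_id, immobile` (one row
#' per second, 0/1/NA). Round-trips are value-identical.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_activity_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           timestamp = readr::col_datetime(),
                           cage_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  attr(out$timestamp, "tzone") <- "UTC"
  out
}

#' @rdname read_activity_csv
#' @param data Tibble to write.
#' @export
write_activity_csv <- function(data, path) {
  data$timestamp <- format(data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname read_activity_csv
#' @export
read_immobility_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           timestamp = readr::col_datetime(),
                           cage_id = readr::col_character(),
                           immobile = readr::col_integer()
                         ))
  attr(out$timestamp, "tzone") <- "UTC"
  out
}

#' @rdname read_activity_csv
#' @export
write_immobility_csv <- function(data, path) {
  data$timestamp <- format(data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(data, path)
  invisible(path)
}

#' Read/write cage metadata
#'
#' Layout: `cage_id, genotype, sex, n_animals, cohort, cage_change_dates`
#' with `cage_change_dates` a semicolon-separated list of ISO dates. On read,
#' dates become a list-column of `Date`s. Cages house two same-sex, same-
#' genotype animals; the cage is the experimental unit throughout.
#'
#' @param path CSV file path.
#' @return Metadata tibble.
#' @export
read_cage_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cage_id = readr::col_character(),
                          genotype = readr::col_character(),
                          sex = readr::col_character(),
                          n_animals = readr::col_integer(),
                          cohort = readr::col_character(),
                          cage_change_dates = readr::col_character()
                        ))
  validate_metadata_fields(md)
  md$cage_change_dates <- lapply(
    strsplit(ifelse(is.na(md$cage_change_dates), "", md$cage_change_dates), ";", fixed = TRUE),
    function(x) as.Date(x[nzchar(x)])
  )
  md
}

#' @rdname read_cage_metadata
#' @param data Metadata tibble (list-column or string `cage_change_dates`).
#' @export
write_cage_metadata <- function(data, path) {
  if (is.list(data$cage_change_dates)) {
    data$cage_change_dates <- vapply(
      data$cage_change_dates,
      function(x) paste(format(x, "%Y-%m-%d"), collapse = ";"), character(1)
    )
  }
  readr::write_csv(data, path)
  invisible(path)
}

validate_metadata_fields <- function(md) {
  if (!all(md$genotype %in% c("WT", "MUT"))) {
    stop("metadata error: genotype must be WT or MUT", call. = FALSE)
  }
  if (!all(md$sex %in% c("M", "F"))) {
    stop("metadata error: sex must be M or F", call. = FALSE)
  }
  if (!is.null(md$n_animals) && !all(is.na(md$n_animals) | md$n_animals == 2L)) {
    warning("metadata: study design houses two animals per cage", call. = FALSE)
  }
  invisible(md)
}
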