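#' Monitoring blocks of a patient record
#'
#' Hospital stays interrupt monitoring: each admission closes the running
#' block on the admission day and monitoring resumes `pause_days` later.
#' Indices are computed, and gaps imputed, within blocks only — a trend is
#' never interpolated across a hospitalization.
#'
#' @param record a [patient_record()].
#' @param pause_days pause after each admission (days).
#' @return data frame with one row per block: `block`, `start`, `end`
#'   (`Date`, inclusive). Blocks shorter than one day are dropped.
#' @export
monitoring_blocks <- function(record, pause_days = 7) {
  stopifnot(inherits(record, "patient_record"))
  adm <- record$events$admission_date
  bounds_start <- record$monitoring_start
  out <- list()
  b <- 1L
  for (a in seq_along(adm)) {
    if (adm[a] < bounds_start) next  # admission during a previous pause
    out[[b]] <- data.frame(block = b, start = bounds_start, end = adm[a])
    bounds_start <- adm[a] + pause_days + 1
    b <- b + 1L
  }
  if (bounds_start <= record$monitoring_end) {
    out[[b]] <- data.frame(block = b, start = bounds_start,
                           end = record$monitoring_end)
  }
  if (!length(out))
    return(data.frame(block = integer(), start = as.Date(character()),
                      end = as.Date(character())))
  do.call(rbind, out)
}

#' Prepare a measurement series on a contiguous daily grid
#'
#' Builds the daily grid from the first to the last observation (optionally
#' within explicit bounds) and linearly interpolates interior gaps. Each grid
#' day is flagged `observed`, `imputed`, or `missing`. Imputation is causal in
#' the real-time sense: the interpolated value for a gap day only ever
#' depends on its two bracketing observations, so it becomes available the
#' moment the later bracketing observation arrives and is reproducible from
#' observations up to that date. Leading days before the first observation
#' and trailing days after the last are `missing`, never imputed.
#'
#' @param series a [measurement_series()] with at least one entry in bounds.
#' @param from,to optional `Date` bounds for the grid; default to the first
#'   and last observation.
#' @return Object of class `prepared_series`: list with `patient_id`,
#'   `modality`, `dates` (contiguous), `values`, `status`.
#' @export
prepare_series <- function(series, from = NULL, to = NULL) {
  stopifnot(inherits(series, "measurement_series"))
  if (length(series$dates) == 0) stop("cannot prepare an empty series")
  keep <- rep(TRUE, length(series$dates))
  if (!is.null(from)) keep <- keep & series$dates >= as.Date(from)
  if (!is.null(to)) keep <- keep & series$dates <= as.Date(to)
  d <- series$dates[keep]; v <- series$values[keep]
  if (length(d) == 0) stop("no observations within bounds")
  grid_from <- if (is.null(from)) d[1] else as.Date(from)
  grid_to <- if (is.null(to)) d[length(d)] else as.Date(to)
  grid <- seq(grid_from, grid_to, by = "day")
  status <- rep("missing", length(grid))
  values <- rep(NA_real_, length(grid))
  obs_idx <- match(d, grid)
  values[obs_idx] <- v
  status[obs_idx] <- "observed"
  interior <- grid >= d[1] & grid <= d[length(d)] & status == "missing"
  if (any(interior)) {
    if (length(d) >= 2) {
      values[interior] <- approx(as.numeric(d), v,
                                 xout = as.numeric(grid[interior]))$y
    }
    status[interior] <- "imputed"
  }
  structure(list(patient_id = series$patient_id, modality = series$modality,
                 dates = grid, values = values, status = status),
            class = "prepared_series")
}

#' Prepare a patient's series per monitoring block
#'
#' Applies [prepare_series()] within each monitoring block of the record.
#'
#' @param record a [patient_record()].
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @param pause_days hospitalization pause (days).
#' @return List of `prepared_series`, one per block that contains at least
#'   one observation, each carrying its block id as attribute `block`.
#' @export
prepare_record <- function(record, modality, pause_days = 7) {
  stopifnot(inherits(record, "patient_record"))
  s <- record$series[[modality]]
  if (is.null(s)) return(list())
  blocks <- monitoring_blocks(record, pause_days)
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    inb <- s$dates >= blocks$start[i] & s$dates <= blocks$end[i]
    if (!any(inb)) next
    sub <- measurement_series(s$patient_id, s$modality, s$dates[inb],
                              s$values[inb])
    p <- prepare_series(sub)
    attr(p, "block") <- blocks$block[i]
    out[[length(out) + 1L]] <- p
  }
  out
}

#' Weekly adherence counts in a two-week window
#'
#' Counts actual (not imputed) measurements in each 7-day half of a 14-day
#' evaluation window. Under the strict `per_week` rule the window is adherent
#' iff both halves have at least `min_per_week` observed values; the lenient
#' `per_fortnight` rule requires `2 * min_per_week` observations anywhere in
#' the window.
#'
#' @param series a [measurement_series()].
#' @param window_end `Date`; the window covers the 14 days ending on this
#'   day (inclusive).
#' @param min_per_week required observations per week (default 3).
#' @param mode `"per_week"` (strict) or `"per_fortnight"` (lenient).
#' @return List with `counts` (first week, second week) and `adherent`.
#' @export
weekly_adherence <- function(series, window_end, min_per_week = 3,
                             mode = c("per_week", "per_fortnight")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "measurement_series"))
  window_end <- as.Date(window_end)
  window_start <- window_end - 13
  d <- series$dates
  first <- sum(d >= window_start & d <= window_start + 6)
  second <- sum(d > window_start + 6 & d <= window_end)
  adherent <- if (mode == "per_week") {
    first >= min_per_week && second >= min_per_week
  } else {
    (first + second) >= 2 * min_per_week
  }
  list(counts = c(week1 = first, week2 = second), adherent = adherent)
}
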