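#' Construct a measurement series
#'
#' A measurement series holds one patient's dated daily values for one
#' modality. Weight is stored in kilograms; transthoracic bio-impedance is
#' stored after log transform, in log-ohm, under the modality name
#' `"nitti_log_ohm"` so that the transform can never be applied twice.
#'
#' @param patient_id character scalar.
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @param dates `Date` vector, strictly increasing, at most one per day.
#' @param values numeric vector, finite; weight must be positive.
#' @return An object of class `measurement_series`: a list with fields
#'   `patient_id`, `modality`, `dates`, `values`.
#' @export
measurement_series <- function(patient_id, modality, dates, values) {
  modality <- match.arg(modality, c("weight_kg", "nitti_log_ohm"))
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("dates and values must have equal length")
  if (anyNA(dates)) stop("undated measurements in series for ", patient_id)
  if (any(!is.finite(values)))
    stop("non-finite measurement values for ", patient_id)
  if (length(dates) > 1 && any(diff(dates) <= 0))
    stop("dates must be strictly increasing (one measurement per day) for ",
         patient_id)
  if (modality == "weight_kg" && any(values <= 0))
    stop("nonpositive weight for ", patient_id)
  structure(
    list(patient_id = as.character(patient_id), modality = modality,
         dates = dates, values = values),
    class = "measurement_series"
  )
}

#' Construct a patient record
#'
#' Bundles one patient's measurement series, hospitalization events and
#' monitoring interval.
#'
#' @param patient_id character scalar.
#' @param monitoring_start,monitoring_end `Date` scalars bounding the
#'   monitoring interval (inclusive).
#' @param series named list of [measurement_series()], keyed by modality.
#' @param events data frame with columns `admission_date` (`Date`) and
#'   `hf_adjudicated` (logical); zero rows allowed.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, monitoring_start, monitoring_end,
                           series = list(), events = empty_events()) {
  monitoring_start <- as.Date(monitoring_start)
  monitoring_end <- as.Date(monitoring_end)
  if (monitoring_end < monitoring_start)
    stop("monitoring_end before monitoring_start for ", patient_id)
  events <- as.data.frame(events)
  if (!all(c("admission_date", "hf_adjudicated") %in% names(events)))
    stop("events need columns admission_date, hf_adjudicated")
  events$admission_date <- as.Date(events$admission_date)
  events$hf_adjudicated <- as.logical(events$hf_adjudicated)
  events <- events[order(events$admission_date), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 0 &&
      (any(events$admission_date < monitoring_start) ||
       any(events$admission_date > monitoring_end)))
    stop("event outside monitoring interval for patient ", patient_id)
  for (s in series) {
    stopifnot(inherits(s, "measurement_series"))
    if (s$patient_id != patient_id)
      stop("series patient_id does not match record ", patient_id)
    if (length(s$dates) &&
        (s$dates[1] < monitoring_start ||
         s$dates[length(s$dates)] > monitoring_end))
      stop("measurements outside monitoring interval for ", patient_id)
  }
  names(series) <- vapply(series, `[[`, "", "modality")
  structure(
    list(patient_id = as.character(patient_id),
         monitoring_start = monitoring_start,
         monitoring_end = monitoring_end,
         series = series, events = events),
    class = "patient_record"
  )
}

empty_events <- function() {
  data.frame(admission_date = as.Date(character()),
             hf_adjudicated = logical())
}

#' Construct a cohort
#'
#' @param records list of [patient_record()] objects with unique patient ids.
#' @param provenance free-text description of where the cohort came from
#'   (file paths or a synthetic-generator configuration).
#' @return An object of class `telealert_cohort`.
#' @export
cohort <- function(records, provenance = "unspecified") {
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort")
  names(records) <- ids
  structure(list(records = records, provenance = provenance),
            class = "telealert_cohort")
}

#' @export
length.telealert_cohort <- function(x) length(x$records)

#' @export
print.telealert_cohort <- function(x, ...) {
  n_ev <- sum(vapply(x$records, function(r) nrow(r$events), 0L))
  n_hf <- sum(vapply(x$records,
                     function(r) sum(r$events$hf_adjudicated), 0L))
  days <- sum(vapply(x$records, function(r)
    as.numeric(r$monitoring_end - r$monitoring_start) + 1, 0))
  cat("Telemonitoring cohort:", length(x$records), "patients,",
      n_ev, "hospitalizations (", n_hf, "HF-adjudicated ),",
      round(days / 365.25, 1), "patient-years\n")
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Hospitalization events of a cohort as one table
#'
#' @param x a `telealert_cohort`.
#' @return data frame with columns `patient_id`, `admission_date`,
#'   `hf_adjudicated` (zero rows if the cohort has no events).
#' @export
cohort_events <- function(x) {
  stopifnot(inherits(x, "telealert_cohort"))
  out <- lapply(x$records, function(r) {
    if (nrow(r$events) == 0) return(NULL)
    cbind(patient_id = r$patient_id, r$events)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(patient_id = character(), empty_events())
  rownames(out) <- NULL
  out
}

#' Load a cohort from long-format CSV files
#'
#' Reads daily measurements and adjudicated hospitalization events. Raw
#' impedance values (modality `nitti_ohm`, in ohm) are log-transformed on
#' load — impedance distributions are right-skewed — and stored under the
#' modality `nitti_log_ohm`; weight passes through unchanged.
#'
#' @param measurements_path CSV with columns
#'   `patient_id,date,modality,value`; `modality` is `weight_kg` or
#'   `nitti_ohm`, dates ISO-8601.
#' @param events_path CSV with columns
#'   `patient_id,admission_date,hf_adjudicated`, or `NULL` for no events.
#' @param patients_path optional CSV with columns
#'   `patient_id,monitoring_start,monitoring_end`. When absent, each
#'   patient's monitoring interval is taken as the span of their
#'   measurements.
#' @param log_base base of the impedance log transform; natural log by
#'   default.
#' @return A validated [cohort()].
#' @export
load_cohort <- function(measurements_path, events_path = NULL,
                        patients_path = NULL, log_base = exp(1)) {
  m <- read.csv(measurements_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "date", "modality", "value")
  if (!all(need %in% names(m)))
    stop("measurements file must have columns ", paste(need, collapse = ","))
  m$patient_id <- as.character(m$patient_id)
  m$date <- as.Date(m$date)
  if (anyNA(m$date)) stop("unparseable dates in measurements file")
  bad_mod <- setdiff(unique(m$modality), c("weight_kg", "nitti_ohm"))
  if (length(bad_mod))
    stop("unknown modality: ", paste(bad_mod, collapse = ", "))
  dup <- duplicated(m[c("patient_id", "date", "modality")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate measurement row %d: patient %s, %s, %s",
                 i, m$patient_id[i], format(m$date[i]), m$modality[i]))
  }
  if (any(m$value <= 0)) {
    i <- which(m$value <= 0)[1]
    stop(sprintf("nonpositive value in row %d (patient %s, %s)",
                 i, m$patient_id[i], m$modality[i]))
  }
  is_nitti <- m$modality == "nitti_ohm"
  m$value[is_nitti] <- log(m$value[is_nitti], base = log_base)
  m$modality[is_nitti] <- "nitti_log_ohm"

  ev <- if (is.null(events_path)) {
    cbind(patient_id = character(), empty_events())
  } else {
    e <- read.csv(events_path, stringsAsFactors = FALSE)
    if (nrow(e) == 0) {
      cbind(patient_id = character(), empty_events())
    } else {
      needs <- c("patient_id", "admission_date", "hf_adjudicated")
      if (!all(needs %in% names(e)))
        stop("events file must have columns ", paste(needs, collapse = ","))
      data.frame(patient_id = as.character(e$patient_id),
                 admission_date = as.Date(e$admission_date),
                 hf_adjudicated = as.logical(e$hf_adjudicated))
    }
  }

  intervals <- NULL
  if (!is.null(patients_path)) {
    p <- read.csv(patients_path, stringsAsFactors = FALSE)
    intervals <- data.frame(patient_id = as.character(p$patient_id),
                            monitoring_start = as.Date(p$monitoring_start),
                            monitoring_end = as.Date(p$monitoring_end))
  }

  ids <- unique(c(m$patient_id,
                  if (!is.null(intervals)) intervals$patient_id))
  records <- lapply(ids, function(id) {
    mi <- m[m$patient_id == id, , drop = FALSE]
    ser <- lapply(split(mi, mi$modality), function(x) {
      x <- x[order(x$date), , drop = FALSE]
      measurement_series(id, x$modality[1], x$date, x$value)
    })
    if (!is.null(intervals) && id %in% intervals$patient_id) {
      row <- intervals[intervals$patient_id == id, ]
      start <- row$monitoring_start; end <- row$monitoring_end
    } else {
      if (nrow(mi) == 0) stop("patient ", id, " has no measurements")
      start <- min(mi$date); end <- max(mi$date)
    }
    patient_record(id, start, end, series = ser,
                   events = ev[ev$patient_id == id,
                               c("admission_date", "hf_adjudicated"),
                               drop = FALSE])
  })
  orphan <- setdiff(ev$patient_id, ids)
  if (length(orphan))
    stop("events for unknown patients: ", paste(orphan, collapse = ", "))
  cohort(records, provenance = paste0("files: ", measurements_path, "; ",
                                      if (is.null(events_path)) "(no events)"
                                      else events_path))
}

#' Write a cohort to long-format CSV files
#'
#' Inverse of [load_cohort()]: impedance is exponentiated back to ohm and
#' written under modality `nitti_ohm`. Gaps are preserved — no imputation at
#' I/O. Three files are written: `measurements.csv`, `events.csv` and
#' `patients.csv` (monitoring intervals, so that the round trip is exact even
#' when adherence gaps touch the interval edges).
#'
#' @param x a `telealert_cohort`.
#' @param out_dir directory (created if needed).
#' @param log_base base used when the cohort was loaded/generated.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, out_dir, log_base = exp(1)) {
  stopifnot(inherits(x, "telealert_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rows <- lapply(x$records, function(r) {
    do.call(rbind, lapply(r$series, function(s) {
      v <- s$values
      mod <- s$modality
      if (mod == "nitti_log_ohm") {
        v <- log_base^v
        mod <- "nitti_ohm"
      }
      data.frame(patient_id = s$patient_id, date = format(s$dates),
                 modality = mod,
                 value = sprintf("%.17g", v))
    }))
  })
  meas <- do.call(rbind, rows)
  if (is.null(meas))
    meas <- data.frame(patient_id = character(), date = character(),
                       modality = character(), value = character())
  ev <- cohort_events(x)
  pat <- data.frame(
    patient_id = vapply(x$records, `[[`, "", "patient_id"),
    monitoring_start = vapply(x$records,
                              function(r) format(r$monitoring_start), ""),
    monitoring_end = vapply(x$records,
                            function(r) format(r$monitoring_end), "")
  )
  paths <- file.path(out_dir, c("measurements.csv", "events.csv",
                                "patients.csv"))
  write.csv(meas, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(data.frame(patient_id = ev$patient_id,
                       admission_date = format(ev$admission_date),
                       hf_adjudicated = ev$hf_adjudicated),
            paths[2], row.names = FALSE, quote = FALSE)
  write.csv(pat, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
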