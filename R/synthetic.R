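#' Configuration for the synthetic telemonitoring cohort generator
#'
#' Defaults emulate a chronic heart-failure home-telemonitoring cohort:
#' 91 patients followed for about 10 months, baseline weight around
#' 84 (SD 19) kg, baseline log-impedance around 3.4 (SD 0.3) log-ohm, and an
#' event hazard tuned so that roughly 24 decompensation hospitalizations are
#' expected over the whole cohort. In the `prodrome_days` before each event,
#' weight drifts up linearly by `weight_rise` kg in total and log-impedance
#' drifts down by `nitti_fall` log-ohm (fluid accumulates: weight up,
#' thoracic impedance down), on top of i.i.d. Gaussian day-to-day noise
#' around patient-specific baselines.
#'
#' @param n_patients number of patients.
#' @param monitoring_days_mean,monitoring_days_sd distribution of per-patient
#'   monitoring length (days).
#' @param weight_baseline_mean,weight_baseline_sd baseline weight (kg).
#' @param nitti_baseline_mean,nitti_baseline_sd baseline impedance (log-ohm).
#' @param daily_noise_weight,daily_noise_nitti day-to-day measurement noise
#'   SDs (kg, log-ohm).
#' @param adherence_prob per-day, per-modality probability that the scheduled
#'   measurement was actually taken.
#' @param burst_prob per-day probability of starting a consecutive-day
#'   dropout burst (0 disables burst missingness).
#' @param burst_mean_days mean length of a dropout burst (geometric).
#' @param event_hazard per-patient-day probability of a decompensation
#'   hospitalization.
#' @param prodrome_days length of the pre-event drift (days).
#' @param weight_rise total weight gained over the prodrome (kg).
#' @param nitti_fall total log-impedance lost over the prodrome (log-ohm).
#' @param pause_days monitoring pause after each hospitalization (hospital
#'   stay), days.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 91,
                          monitoring_days_mean = 300,
                          monitoring_days_sd = 45,
                          weight_baseline_mean = 84,
                          weight_baseline_sd = 19,
                          nitti_baseline_mean = 3.4,
                          nitti_baseline_sd = 0.3,
                          daily_noise_weight = 0.6,
                          daily_noise_nitti = 0.06,
                          adherence_prob = 0.8,
                          burst_prob = 0,
                          burst_mean_days = 7,
                          event_hazard = 24 / (91 * 300),
                          prodrome_days = 14,
                          weight_rise = 2.5,
                          nitti_fall = 0.4,
                          pause_days = 7,
                          seed = NULL) {
  cfg <- list(n_patients = n_patients,
              monitoring_days_mean = monitoring_days_mean,
              monitoring_days_sd = monitoring_days_sd,
              weight_baseline_mean = weight_baseline_mean,
              weight_baseline_sd = weight_baseline_sd,
              nitti_baseline_mean = nitti_baseline_mean,
              nitti_baseline_sd = nitti_baseline_sd,
              daily_noise_weight = daily_noise_weight,
              daily_noise_nitti = daily_noise_nitti,
              adherence_prob = adherence_prob,
              burst_prob = burst_prob,
              burst_mean_days = burst_mean_days,
              event_hazard = event_hazard,
              prodrome_days = prodrome_days,
              weight_rise = weight_rise,
              nitti_fall = nitti_fall,
              pause_days = pause_days,
              seed = seed)
  sds <- c("monitoring_days_sd", "weight_baseline_sd", "nitti_baseline_sd",
           "daily_noise_weight", "daily_noise_nitti")
  if (any(unlist(cfg[sds]) < 0)) stop("standard deviations must be >= 0")
  probs <- c("adherence_prob", "burst_prob")
  if (any(unlist(cfg[probs]) < 0 | unlist(cfg[probs]) > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$event_hazard < 0 || cfg$event_hazard > 1)
    stop("event_hazard implies more than one expected event per day")
  if (cfg$prodrome_days < 1) stop("prodrome_days must be >= 1")
  if (cfg$n_patients < 0) stop("n_patients must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# linear prodrome ramp: 0 just before the window, full magnitude on the
# admission day itself
prodrome_ramp <- function(day_offsets, prodrome_days) {
  f <- 1 + day_offsets / prodrome_days  # day_offsets in (-prodrome_days, 0]
  f[day_offsets > 0 | day_offsets <= -prodrome_days] <- 0
  f
}

#' Generate a synthetic telemonitoring cohort
#'
#' Simulates daily weight and log-impedance for each patient: patient-specific
#' Gaussian baselines, i.i.d. daily noise, Bernoulli-thinned adherence
#' (optionally with consecutive-day dropout bursts), hospitalization events
#' drawn from a constant per-day hazard, a linear pre-event drift over the
#' prodrome window, and a monitoring pause of `pause_days` after each
#' admission (hospital stay) after which the signal resumes at baseline.
#'
#' @param config a [cohort_config()].
#' @return A [cohort()]; reproducible given `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    records <- lapply(seq_len(config$n_patients), function(i) {
      simulate_patient(sprintf("P%03d", i), config)
    })
    cohort(records,
           provenance = paste0("synthetic: seed=",
                               if (is.null(config$seed)) "NULL"
                               else config$seed,
                               ", n=", config$n_patients))
  })
}

simulate_patient <- function(id, cfg) {
  n_days <- max(30L, as.integer(round(rnorm(1, cfg$monitoring_days_mean,
                                            cfg$monitoring_days_sd))))
  start <- as.Date("2009-01-01") + sample.int(540L, 1L) - 1L
  w0 <- max(35, rnorm(1, cfg$weight_baseline_mean, cfg$weight_baseline_sd))
  n0 <- rnorm(1, cfg$nitti_baseline_mean, cfg$nitti_baseline_sd)

  # sequential event draws; no event possible during a hospital stay
  event_day <- integer()
  t <- 1L
  while (t <= n_days) {
    if (runif(1) < cfg$event_hazard) {
      event_day <- c(event_day, t)
      t <- t + cfg$pause_days
    }
    t <- t + 1L
  }

  day <- seq_len(n_days)
  trend_w <- numeric(n_days)
  trend_n <- numeric(n_days)
  for (ed in event_day) {
    f <- prodrome_ramp(day - ed, cfg$prodrome_days)
    trend_w <- trend_w + cfg$weight_rise * f
    trend_n <- trend_n - cfg$nitti_fall * f
  }

  in_pause <- rep(FALSE, n_days)
  for (ed in event_day) {
    span <- seq.int(ed + 1L, min(ed + cfg$pause_days, n_days))
    if (ed < n_days) in_pause[span] <- TRUE
  }

  w_vals <- w0 + trend_w + rnorm(n_days, 0, cfg$daily_noise_weight)
  n_vals <- n0 + trend_n + rnorm(n_days, 0, cfg$daily_noise_nitti)
  w_vals <- pmax(w_vals, 1)  # weight must stay positive

  take_w <- adherence_mask(n_days, cfg) & !in_pause
  take_n <- adherence_mask(n_days, cfg) & !in_pause

  ser <- list()
  if (any(take_w))
    ser$weight_kg <- measurement_series(id, "weight_kg",
                                        start + day[take_w] - 1L,
                                        w_vals[take_w])
  if (any(take_n))
    ser$nitti_log_ohm <- measurement_series(id, "nitti_log_ohm",
                                            start + day[take_n] - 1L,
                                            n_vals[take_n])
  events <- if (length(event_day)) {
    data.frame(admission_date = start + event_day - 1L,
               hf_adjudicated = TRUE)
  } else empty_events()
  patient_record(id, start, start + n_days - 1L, series = ser,
                 events = events)
}

adherence_mask <- function(n_days, cfg) {
  keep <- runif(n_days) < cfg$adherence_prob
  if (cfg$burst_prob > 0) {
    t <- 1L
    while (t <= n_days) {
      if (runif(1) < cfg$burst_prob) {
        len <- 1L + stats::rgeom(1, 1 / cfg$burst_mean_days)
        keep[seq.int(t, min(t + len - 1L, n_days))] <- FALSE
        t <- t + len
      }
      t <- t + 1L
    }
  }
  keep
}

#' Inject a deterministic decompensation event into a patient record
#'
#' Adds a linear prodrome drift to the existing measurement values in the
#' `prodrome_days` window ending on the admission day (weight up by
#' `weight_rise`, log-impedance down by `nitti_fall`, reaching the full
#' magnitude on the admission day) and registers the hospitalization.
#' Existing noise is untouched. Useful for building fixtures with events at
#' known positions.
#'
#' @param record a [patient_record()].
#' @param admission_date `Date`, inside the monitoring interval.
#' @param prodrome_days,weight_rise,nitti_fall drift specification, as in
#'   [cohort_config()].
#' @param hf_adjudicated logical flag for the new event.
#' @return The modified `patient_record`. If the prodrome window would extend
#'   before monitoring start it is truncated, with a warning.
#' @export
inject_event <- function(record, admission_date, prodrome_days = 14,
                         weight_rise = 2.5, nitti_fall = 0.4,
                         hf_adjudicated = TRUE) {
  stopifnot(inherits(record, "patient_record"))
  admission_date <- as.Date(admission_date)
  if (admission_date < record$monitoring_start ||
      admission_date > record$monitoring_end)
    stop("admission_date outside monitoring interval")
  if (admission_date - prodrome_days + 1 < record$monitoring_start)
    warning("prodrome extends before monitoring start; truncated")
  shift <- c(weight_kg = weight_rise, nitti_log_ohm = -nitti_fall)
  for (mod in names(record$series)) {
    s <- record$series[[mod]]
    f <- prodrome_ramp(as.numeric(s$dates - admission_date), prodrome_days)
    record$series[[mod]]$values <- s$values + shift[[mod]] * f
  }
  ev <- rbind(record$events,
              data.frame(admission_date = admission_date,
                         hf_adjudicated = hf_adjudicated))
  ev <- ev[order(ev$admission_date), , drop = FALSE]
  rownames(ev) <- NULL
  record$events <- ev
  record
}
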