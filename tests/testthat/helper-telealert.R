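# Independent brute-force oracles and fixture builders shared across tests.
# Oracles are written as plain loops over the definitions, deliberately not
# reusing any package internals.

oracle_rot <- function(x, d) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) if (t - d >= 1) out[t] <- x[t] - x[t - d]
  out
}

oracle_macd <- function(x, ns, nl) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t < nl) next
    out[t] <- mean(x[(t - ns + 1):t]) - mean(x[(t - nl + 1):t])
  }
  out
}

oracle_cusum <- function(x, d, c, direction, floor = 1e-6) {
  n <- length(x)
  out <- rep(NA_real_, n)
  s <- 0
  for (t in seq_len(n)) {
    if (t <= d) next
    w <- x[(t - d):(t - 1)]
    z <- (x[t] - mean(w)) / max(sd(w), floor)
    s <- if (direction == "decrease") min(0, s + z + c) else max(0, s + z - c)
    out[t] <- s
  }
  out
}

# measurement series with random interior gaps
random_series <- function(n_days = 60, p_obs = 0.8, sd = 1, baseline = 10,
                          modality = "nitti_log_ohm", id = "PX",
                          start = as.Date("2020-01-01")) {
  keep <- runif(n_days) < p_obs
  keep[1] <- TRUE; keep[n_days] <- TRUE
  days <- which(keep)
  measurement_series(id, modality, start + days - 1,
                     baseline + rnorm(length(days), 0, sd))
}

prepared_from_values <- function(values, id = "PX",
                                 modality = "nitti_log_ohm",
                                 start = as.Date("2020-01-01")) {
  prepare_series(measurement_series(id, modality,
                                    start + seq_along(values) - 1, values))
}

# fully observed flat record, optionally with events injected later
flat_record <- function(id = "P1", n_days = 120, weight = 80, nitti = 3.4,
                        start = as.Date("2020-01-01")) {
  days <- start + seq_len(n_days) - 1
  patient_record(
    id, start, start + n_days - 1,
    series = list(
      measurement_series(id, "weight_kg", days, rep(weight, n_days)),
      measurement_series(id, "nitti_log_ohm", days, rep(nitti, n_days))
    ))
}

# small deterministic cohort: n single-event patients + m event-free ones
toy_cohort <- function(n_event = 8, n_free = 8, n_days = 150,
                       event_day = 100, noise = 0, seed = 42,
                       prodrome_days = 14, weight_rise = 2.5,
                       nitti_fall = 0.4) {
  set.seed(seed)
  recs <- list()
  for (i in seq_len(n_event + n_free)) {
    id <- sprintf("T%02d", i)
    start <- as.Date("2020-01-01")
    days <- start + seq_len(n_days) - 1
    r <- patient_record(
      id, start, start + n_days - 1,
      series = list(
        measurement_series(id, "weight_kg", days,
                           80 + rnorm(n_days, 0, noise)),
        measurement_series(id, "nitti_log_ohm", days,
                           3.4 + rnorm(n_days, 0, noise))
      ))
    if (i <= n_event)
      r <- inject_event(r, start + event_day - 1,
                        prodrome_days = prodrome_days,
                        weight_rise = weight_rise, nitti_fall = nitti_fall)
    recs[[i]] <- r
  }
  cohort(recs, provenance = "test fixture")
}

# labeled-period table for feeding the ROC machinery directly
fake_periods <- function(event_peaks, non_event_peaks) {
  data.frame(
    patient_id = "PX",
    label = c(rep("event", length(event_peaks)),
              rep("non_event", length(non_event_peaks))),
    peak_index = c(event_peaks, non_event_peaks))
}
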