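new_output_index <- function(prepared, values, algorithm, direction, params) {
  structure(
    list(patient_id = prepared$patient_id, algorithm = algorithm,
         direction = direction, params = params,
         dates = prepared$dates, values = values,
         block = attr(prepared, "block") %||% 1L),
    class = "output_index"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected alert direction for a modality
#'
#' Decompensation raises weight (fluid retention) and lowers thoracic
#' impedance (pulmonary congestion), so weight indices alert on increases and
#' impedance indices on decreases.
#'
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @return `"increase"` or `"decrease"`.
#' @export
modality_direction <- function(modality) {
  switch(modality,
         weight_kg = "increase",
         nitti_log_ohm = "decrease",
         stop("unknown modality ", modality))
}

#' Rule-of-thumb (RoT) output index
#'
#' The simplest alert statistic: the difference between today's value and the
#' value `d` days earlier on the imputed daily grid,
#' `index(t) = x(t) - x(t - d)`. Noisy and fast; a chance reading moves it as
#' much as a real trend does.
#'
#' @param prepared a [prepare_series()] result.
#' @param d day lag, integer >= 1.
#' @return An `output_index` (values `NA` during the `d`-day warm-up and
#'   wherever either operand is missing).
#' @export
rot_index <- function(prepared, d) {
  stopifnot(inherits(prepared, "prepared_series"))
  if (d < 1) stop("d must be >= 1")
  d <- as.integer(d)
  x <- prepared$values
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n > d) out[(d + 1):n] <- x[(d + 1):n] - x[1:(n - d)]
  new_output_index(prepared, out, "RoT", NA_character_, list(d = d))
}

trailing_sma <- function(x, n) {
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, length(x))
  if (length(x) >= n) {
    idx <- n:length(x)
    out[idx] <- (cs[idx + 1] - cs[idx + 1 - n]) / n
  }
  out
}

#' Moving-average convergence divergence (MACD) output index
#'
#' Difference between a short and a long simple trailing moving average over
#' the imputed daily grid: positive when the recent level exceeds the long-run
#' level. Smooths out day-to-day fluctuation and follows gradual trends in
#' either direction.
#'
#' @param prepared a [prepare_series()] result.
#' @param n_short,n_long window lengths in days, `1 <= n_short < n_long`.
#' @return An `output_index` with a warm-up of `n_long - 1` days.
#' @export
macd_index <- function(prepared, n_short, n_long) {
  stopifnot(inherits(prepared, "prepared_series"))
  if (n_short < 1) stop("n_short must be >= 1")
  if (n_short >= n_long) stop("n_short must be smaller than n_long")
  out <- trailing_sma(prepared$values, as.integer(n_short)) -
    trailing_sma(prepared$values, as.integer(n_long))
  new_output_index(prepared, out, "MACD", NA_character_,
                   list(n_short = as.integer(n_short),
                        n_long = as.integer(n_long)))
}

#' One-sided standardized CUSUM output index
#'
#' A cumulative-sum control chart on standardized deviations. Each day is
#' scored against the trailing `d`-day running mean and SD (current day
#' excluded, so a sudden deviation is judged against the pre-deviation
#' baseline): `z_t = (x_t - mean_t) / max(sd_t, sigma_floor)`. The sum then
#' accumulates deviations beyond the allowance `c`, clamped one-sided:
#' decrease direction `S_t = min(0, S_[t-1] + z_t + c)`, increase direction
#' `S_t = max(0, S_[t-1] + z_t - c)`. The chart starts at 0 after the
#' `d`-day warm-up and is reset at every monitoring-block start (monitoring
#' onset and each post-hospitalization resumption). Sustained drift
#' accumulates; isolated noise is absorbed by the allowance.
#'
#' @param prepared a [prepare_series()] result.
#' @param d running-statistics window, integer >= 2.
#' @param c allowance (depreciation) per step, >= 0, in SD units.
#' @param direction `"increase"` or `"decrease"`.
#' @param sigma_floor lower bound for the running SD, guarding constant
#'   windows.
#' @return An `output_index`; `<= 0` everywhere for `"decrease"`, `>= 0` for
#'   `"increase"`.
#' @export
cusum_index <- function(prepared, d, c, direction = c("increase", "decrease"),
                        sigma_floor = 1e-6) {
  stopifnot(inherits(prepared, "prepared_series"))
  direction <- match.arg(direction)
  if (d < 2) stop("d must be >= 2")
  if (c < 0) stop("c must be >= 0")
  d <- as.integer(d)
  x <- prepared$values
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n > d) {
    cs <- cumsum(c(0, x))
    cs2 <- cumsum(c(0, x^2))
    t <- (d + 1):n
    mu <- (cs[t] - cs[t - d]) / d
    ss <- pmax(0, (cs2[t] - cs2[t - d]) - d * mu^2)
    sdev <- sqrt(ss / (d - 1))
    z <- (x[t] - mu) / pmax(sdev, sigma_floor)
    s <- 0
    if (direction == "decrease") {
      for (i in seq_along(t)) {
        s <- min(0, s + z[i] + c)
        out[t[i]] <- s
      }
    } else {
      for (i in seq_along(t)) {
        s <- max(0, s + z[i] - c)
        out[t[i]] <- s
      }
    }
  }
  new_output_index(prepared, out, "CUSUM", direction,
                   list(d = d, c = c, sigma_floor = sigma_floor))
}

#' Compute an output index for one patient record
#'
#' Convenience wrapper: prepares the record per monitoring block, computes
#' the requested index in each block (the chart restarts after every
#' hospitalization), and concatenates.
#'
#' @param record a [patient_record()].
#' @param algorithm `"rot"`, `"macd"` or `"cusum"`.
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @param params named list of algorithm parameters (`d`; `n_short`/`n_long`;
#'   `d`/`c`).
#' @param pause_days hospitalization pause (days).
#' @return data frame with columns `date`, `value`, `block` and attributes
#'   `algorithm`, `direction`, `params`, `patient_id`.
#' @export
record_index <- function(record, algorithm = c("rot", "macd", "cusum"),
                         modality, params, pause_days = 7) {
  algorithm <- match.arg(algorithm)
  direction <- modality_direction(modality)
  preps <- prepare_record(record, modality, pause_days)
  parts <- lapply(preps, function(p) {
    idx <- switch(algorithm,
                  rot = rot_index(p, params$d),
                  macd = macd_index(p, params$n_short, params$n_long),
                  cusum = cusum_index(p, params$d, params$c,
                                      direction = direction))
    data.frame(date = idx$dates, value = idx$values, block = idx$block)
  })
  out <- if (length(parts)) do.call(rbind, parts) else
    data.frame(date = as.Date(character()), value = numeric(),
               block = integer())
  attr(out, "algorithm") <- algorithm
  attr(out, "direction") <- direction
  attr(out, "params") <- params
  attr(out, "patient_id") <- record$patient_id
  out
}

#' Threshold alerts from an output index
#'
#' An alert fires when the index crosses the threshold in the alert
#' direction: `index > threshold` for `"increase"`, `index < threshold` for
#' `"decrease"` (decrease thresholds are negative). Days with an undefined
#' index (warm-up, missing data) never alert.
#'
#' @param index data frame with columns `date`, `value` (e.g. from
#'   [record_index()]), or an `output_index`.
#' @param threshold finite numeric.
#' @param direction `"increase"` or `"decrease"`.
#' @return data frame `date`, `alert` (logical).
#' @export
threshold_alerts <- function(index, threshold,
                             direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric")
  if (direction == "increase" && threshold < 0)
    warning("increase direction with a negative threshold")
  if (direction == "decrease" && threshold > 0)
    warning("decrease direction with a positive threshold")
  if (inherits(index, "output_index"))
    index <- data.frame(date = index$dates, value = index$values)
  fired <- if (direction == "increase") index$value > threshold
           else index$value < threshold
  fired[is.na(fired)] <- FALSE
  data.frame(date = index$date, alert = fired)
}

#' Published guideline and literature weight rules
#'
#' Threshold rules for daily weight proposed by heart-failure guidelines and
#' earlier telemonitoring studies. Each rule is one or more (threshold kg,
#' over n days) clauses combined by OR; thresholds quoted in pounds are
#' converted at 0.45 kg/lb. One preset (`zhang_macd`) is a moving-average
#' rule rather than a day difference.
#'
#' @return Named list of rules. Each rule is a list with `source`, `type`
#'   (`"rot"` or `"macd"`), and `clauses` — for `"rot"`, a data frame
#'   `threshold_kg`, `days`; for `"macd"`, a list `threshold_kg`, `n_short`,
#'   `n_long`.
#' @export
guideline_rules <- function() {
  rot_rule <- function(source, thr_kg, days)
    list(source = source, type = "rot",
         clauses = data.frame(threshold_kg = thr_kg, days = days))
  lb <- function(x) x * LBS_TO_KG
  list(
    hfsa_2lb_1d = rot_rule("HFSA: >2 lbs in 1 day", lb(2), 1),
    esc_2kg_3d = rot_rule("ESC: >2 kg in 3 days", 2, 3),
    hfsa_4lb_1wk = rot_rule("HFSA: >4 lbs in 1 week", lb(4), 7),
    abraham_2lb1d_3lb3d = rot_rule(
      "Abraham: >2 lbs in 1 day or >3 lbs in 3 days",
      lb(c(2, 3)), c(1, 3)),
    abraham_2lb1d_5lb3d = rot_rule(
      "Abraham: >2 lbs in 1 day or >5 lbs in 3 days",
      lb(c(2, 5)), c(1, 3)),
    abraham_3lb1d_5lb3d = rot_rule(
      "Abraham: >3 lbs in 1 day or >5 lbs in 3 days",
      lb(c(3, 5)), c(1, 3)),
    abraham_3lb1d_7lb3d = rot_rule(
      "Abraham: >3 lbs in 1 day or >7 lbs in 3 days",
      lb(c(3, 7)), c(1, 3)),
    abraham_4lb1d_7lb3d = rot_rule(
      "Abraham: >4 lbs in 1 day or >7 lbs in 3 days",
      lb(c(4, 7)), c(1, 3)),
    abraham_4lb1d_9lb3d = rot_rule(
      "Abraham: >4 lbs in 1 day or >9 lbs in 3 days",
      lb(c(4, 9)), c(1, 3)),
    abraham_5lb1d_9lb3d = rot_rule(
      "Abraham: >5 lbs in 1 day or >9 lbs in 3 days",
      lb(c(5, 9)), c(1, 3)),
    chaudhry_2lb_1wk = rot_rule("Chaudhry: >2 lbs in 1 week", lb(2), 7),
    chaudhry_5lb_1wk = rot_rule("Chaudhry: >5 lbs in 1 week", lb(5), 7),
    zhang_macd = list(source = "Zhang: >4 lbs in a 5 to 80 days MACD",
                      type = "macd",
                      clauses = list(threshold_kg = lb(4),
                                     n_short = 5, n_long = 80))
  )
}

#' Alerts from a guideline weight rule
#'
#' Evaluates every clause of a preset rule on the prepared weight series and
#' fires on any clause exceedance.
#'
#' @param prepared a [prepare_series()] result (weight, kg).
#' @param rule one element of [guideline_rules()], or its name.
#' @return data frame `date`, `alert`.
#' @export
guideline_alerts <- function(prepared, rule) {
  if (is.character(rule)) {
    rules <- guideline_rules()
    if (!rule %in% names(rules)) stop("unknown preset ", rule)
    rule <- rules[[rule]]
  }
  if (rule$type == "macd") {
    idx <- macd_index(prepared, rule$clauses$n_short, rule$clauses$n_long)
    return(threshold_alerts(idx, rule$clauses$threshold_kg, "increase"))
  }
  fired <- rep(FALSE, length(prepared$dates))
  for (i in seq_len(nrow(rule$clauses))) {
    idx <- rot_index(prepared, rule$clauses$days[i])
    a <- idx$values > rule$clauses$threshold_kg[i]
    a[is.na(a)] <- FALSE
    fired <- fired | a
  }
  data.frame(date = prepared$dates, alert = fired)
}

#' Cross-validated optimal parameter presets
#'
#' Parameter/threshold combinations reported as optimal for each algorithm
#' and modality in the study this package's evaluation design follows
#' (thresholds at the maximum Youden index within 90-100% specificity).
#' Useful as sensible starting points for real weight / log-impedance data.
#'
#' @return data frame with columns `modality`, `algorithm`, `params`
#'   (list-column), `threshold`, `direction`.
#' @export
optimal_presets <- function() {
  data.frame(
    modality = c("weight_kg", "weight_kg", "weight_kg",
                 "nitti_log_ohm", "nitti_log_ohm", "nitti_log_ohm"),
    algorithm = rep(c("rot", "macd", "cusum"), 2),
    threshold = c(2.7, 0.62, 8.7, -0.27, -0.059, -7.8),
    direction = rep(c("increase", "decrease"), each = 3),
    params = I(list(list(d = 17), list(n_short = 9, n_long = 20),
                    list(d = 10, c = 0.75),
                    list(d = 21), list(n_short = 9, n_long = 35),
                    list(d = 20, c = 0.75)))
  )
}
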