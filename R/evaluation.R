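#' Segment a patient record into two-week evaluation periods
#'
#' The monitoring time is divided into 14-day windows such that a window
#' containing an HF-adjudicated hospitalization ends on the admission day.
#' Within each monitoring block that ends in an HF admission, windows are
#' tiled backward from the admission; the leftover partial window at the
#' block start is discarded. Blocks that end at a non-HF admission, and the
#' final block, are tiled forward from the block start with the trailing
#' partial window discarded. Short leftover stretches at the start or end of
#' monitoring and directly after a hospitalization therefore drop out of the
#' analysis. Days covered by periods, discarded days and hospitalization
#' pauses partition the monitoring interval exactly.
#'
#' @param record a [patient_record()].
#' @param pause_days monitoring pause after each admission (days).
#' @return data frame with columns `patient_id`, `start`, `end` (`Date`,
#'   14 days inclusive) and `label` (`"event"` or `"non_event"`); zero rows
#'   if the record is shorter than 14 days.
#' @export
segment_periods <- function(record, pause_days = 7) {
  stopifnot(inherits(record, "patient_record"))
  blocks <- monitoring_blocks(record, pause_days)
  adm_hf <- record$events$admission_date[record$events$hf_adjudicated]
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    bs <- blocks$start[i]; be <- blocks$end[i]
    len <- as.numeric(be - bs) + 1
    n_win <- len %/% 14
    if (n_win == 0) next
    ends_in_hf <- be %in% adm_hf
    if (ends_in_hf) {
      ends <- be - 14 * (seq_len(n_win) - 1)  # backward from admission
      labels <- c("event", rep("non_event", n_win - 1))
    } else {
      ends <- bs + 14 * seq_len(n_win) - 1    # forward from block start
      labels <- rep("non_event", n_win)
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = record$patient_id, start = ends - 13, end = ends,
      label = labels)
  }
  if (!length(out))
    return(data.frame(patient_id = character(), start = as.Date(character()),
                      end = as.Date(character()), label = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label evaluation periods with adherence and peak index
#'
#' Attaches to each period the number of observed measurements per week, the
#' adherence flag, and the most extreme index value in the window (maximum
#' for increase-direction indices, minimum for decrease). Periods that fail
#' adherence — including event-ending periods, which are excluded rather than
#' counted as missed detections — and periods with no defined index value
#' (algorithm warm-up) are dropped.
#'
#' @param periods output of [segment_periods()].
#' @param index data frame `date`, `value` from [record_index()].
#' @param series the raw [measurement_series()] used for adherence counting.
#' @param direction `"increase"` or `"decrease"`.
#' @param min_per_week,adherence_mode see [weekly_adherence()].
#' @return The eligible periods with columns `peak_index`, `adherent` added.
#' @export
label_periods <- function(periods, index, series,
                          direction = c("increase", "decrease"),
                          min_per_week = 3,
                          adherence_mode = c("per_week", "per_fortnight")) {
  direction <- match.arg(direction)
  adherence_mode <- match.arg(adherence_mode)
  if (nrow(periods) == 0) {
    periods$peak_index <- numeric(0)
    periods$adherent <- logical(0)
    return(periods)
  }
  peak_fun <- if (direction == "increase") max else min
  peak <- rep(NA_real_, nrow(periods))
  adherent <- logical(nrow(periods))
  for (i in seq_len(nrow(periods))) {
    adherent[i] <- weekly_adherence(series, periods$end[i],
                                    min_per_week = min_per_week,
                                    mode = adherence_mode)$adherent
    v <- index$value[index$date >= periods$start[i] &
                       index$date <= periods$end[i]]
    v <- v[!is.na(v)]
    if (length(v)) peak[i] <- peak_fun(v)
  }
  periods$peak_index <- peak
  periods$adherent <- adherent
  out <- periods[adherent & !is.na(peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confusion counts of labeled periods at a threshold
#'
#' An event-ending period whose peak index crosses the threshold is a true
#' positive, otherwise a false negative; a non-event period that crosses is a
#' false positive, otherwise a true negative.
#'
#' @param periods labeled periods with `label` and `peak_index` columns.
#' @param threshold alert threshold.
#' @param direction `"increase"` (cross: peak > threshold) or `"decrease"`
#'   (peak < threshold).
#' @return List with `counts` (TP, FP, TN, FN) and `metrics` (sensitivity,
#'   specificity, ppv, npv; `NA` where the denominator is empty).
#' @export
confusion_at_threshold <- function(periods, threshold,
                                   direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  cross <- if (direction == "increase") periods$peak_index > threshold
           else periods$peak_index < threshold
  is_event <- periods$label == "event"
  tp <- sum(cross & is_event); fn <- sum(!cross & is_event)
  fp <- sum(cross & !is_event); tn <- sum(!cross & !is_event)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = c(sensitivity = ratio(tp, tp + fn),
                   specificity = ratio(tn, tn + fp),
                   ppv = ratio(tp, tp + fp),
                   npv = ratio(tn, tn + fn)))
}

#' ROC curve over period peak indices
#'
#' Sweeps the alert threshold over all distinct peak values and records
#' (threshold, sensitivity, specificity) at each. The curve always contains
#' the two trivial operating points: alert never (sensitivity 0, specificity
#' 1) and alert always (sensitivity 1, specificity 0).
#'
#' @param periods labeled periods (both classes must be present).
#' @param direction `"increase"` or `"decrease"`.
#' @return Object of class `telealert_roc`: data frame `threshold`,
#'   `sensitivity`, `specificity` with attribute `direction`.
#' @export
roc_curve <- function(periods, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!any(periods$label == "event") || !any(periods$label != "event"))
    stop("ROC needs at least one event and one non-event period")
  is_event <- periods$label == "event"
  pe <- sort(periods$peak_index[is_event])
  pn <- sort(periods$peak_index[!is_event])
  peaks <- sort(unique(periods$peak_index))
  if (direction == "increase") {
    thr <- c(-Inf, peaks)
    sens <- (length(pe) - findInterval(thr, pe)) / length(pe)  # peak > thr
    spec <- findInterval(thr, pn) / length(pn)                 # peak <= thr
  } else {
    thr <- c(Inf, rev(peaks))
    tp <- findInterval(thr, pe, left.open = TRUE)              # peak < thr
    sens <- tp / length(pe)
    spec <- 1 - findInterval(thr, pn, left.open = TRUE) / length(pn)
  }
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  structure(out, direction = direction, class = c("telealert_roc",
                                                  "data.frame"))
}

#' Partial area under the ROC curve at high specificity
#'
#' Trapezoidal area of the ROC staircase restricted to specificity in
#' `[spec_min, 1]`, normalized to `[0, 1]` by dividing by `1 - spec_min`.
#'
#' @param roc a [roc_curve()] result.
#' @param spec_min lower specificity bound (e.g. 0.95).
#' @return Normalized partial AUC in `[0, 1]`.
#' @export
partial_auc <- function(roc, spec_min = 0.95) {
  stopifnot(spec_min >= 0, spec_min < 1)
  # one point per specificity: the best sensitivity attainable there
  ord <- order(roc$specificity, -roc$sensitivity)
  spec <- roc$specificity[ord]; sens <- roc$sensitivity[ord]
  first <- !duplicated(spec)
  pts <- data.frame(spec = spec[first], sens = sens[first])
  if (spec_min > min(pts$spec)) {
    sens_at <- approx(pts$spec, pts$sens, xout = spec_min, ties = max)$y
    pts <- pts[pts$spec >= spec_min, , drop = FALSE]
    pts <- rbind(data.frame(spec = spec_min, sens = sens_at), pts)
  }
  if (nrow(pts) == 1) return(pts$sens)
  area <- sum(diff(pts$spec) * (head(pts$sens, -1) + tail(pts$sens, -1)) / 2)
  area / (1 - spec_min)
}

#' Youden operating point constrained to high specificity
#'
#' Among ROC points with specificity strictly above `spec_min`, returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1, ties
#' broken toward higher specificity. If no point satisfies the constraint the
#' most specific available point is returned with a warning.
#'
#' @param roc a [roc_curve()] result.
#' @param spec_min specificity constraint (default 0.90).
#' @return List `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(roc, spec_min = 0.90) {
  ok <- roc$specificity > spec_min
  if (!any(ok)) {
    warning("no operating point with specificity > ", spec_min,
            "; returning the most specific point")
    ok <- roc$specificity == max(roc$specificity)
  }
  cand <- roc[ok, , drop = FALSE]
  j <- cand$sensitivity + cand$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(cand$specificity[best])]
  list(threshold = cand$threshold[best],
       sensitivity = cand$sensitivity[best],
       specificity = cand$specificity[best],
       youden = j[best])
}

#' False alarms per patient-year
#'
#' Merges consecutive alert days into alert episodes; an episode is a false
#' alarm iff no HF-adjudicated hospitalization occurs within `grace_days`
#' after its onset. The rate is false episodes divided by total monitoring
#' time. A single sustained alert spanning several two-week windows counts
#' several window false positives but only one false alarm here.
#'
#' @param alerts named list (by patient id) of data frames `date`, `alert`.
#' @param x the `telealert_cohort` the alerts were computed on.
#' @param grace_days days after episode onset within which an HF admission
#'   makes the episode true (default 14, mirroring the detection window).
#' @return List `rate` (false alarms / patient-year), `false_episodes`,
#'   `episodes`, `patient_years`.
#' @export
false_alarm_rate <- function(alerts, x, grace_days = 14) {
  stopifnot(inherits(x, "telealert_cohort"))
  days <- sum(vapply(x$records, function(r)
    as.numeric(r$monitoring_end - r$monitoring_start) + 1, 0))
  if (days <= 0) stop("cohort has no follow-up time")
  n_ep <- 0L; n_false <- 0L
  for (id in names(alerts)) {
    a <- alerts[[id]]
    a <- a[order(a$date), , drop = FALSE]
    on <- a$date[a$alert]
    if (!length(on)) next
    # episode onsets: alert days not preceded by an alert on the previous day
    onset <- on[c(TRUE, diff(on) > 1)]
    rec <- x$records[[id]]
    adm <- rec$events$admission_date[rec$events$hf_adjudicated]
    for (o in seq_along(onset)) {
      n_ep <- n_ep + 1L
      hit <- any(adm >= onset[o] & adm <= onset[o] + grace_days)
      if (!hit) n_false <- n_false + 1L
    }
  }
  list(rate = n_false / (days / 365.25), false_episodes = n_false,
       episodes = n_ep, patient_years = days / 365.25)
}

#' Compare period means with a patient-level mixed-effect model
#'
#' Tests whether values in the two weeks preceding a decompensation differ
#' from values in all other periods, using a linear mixed model with
#' patient-specific random intercepts: `value ~ label + (1 | patient)`. If
#' the fit is singular or fails, falls back to a patient-cluster permutation
#' test of the label effect, with a warning.
#'
#' @param values numeric vector (raw measurements or output-index values).
#' @param labels factor/character, `"event"` vs anything else.
#' @param patient_ids vector of patient identifiers, same length.
#' @param n_perm permutations for the fallback test.
#' @return List `estimate` (event minus non-event fixed effect), `p_value`,
#'   `method`.
#' @export
compare_period_means <- function(values, labels, patient_ids,
                                 n_perm = 999) {
  stopifnot(length(values) == length(labels),
            length(values) == length(patient_ids))
  if (length(unique(patient_ids)) < 2) stop("need at least two patients")
  df <- data.frame(value = as.numeric(values),
                   event = factor(labels == "event", c(FALSE, TRUE)),
                   patient = factor(patient_ids))
  if (stats::var(df$value) == 0)
    return(list(estimate = 0, p_value = 1, method = "degenerate"))
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(value ~ event + (1 | patient),
                                    data = df)),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    co <- stats::coef(summary(fit))
    return(list(estimate = unname(co["eventTRUE", "Estimate"]),
                p_value = unname(co["eventTRUE", "Pr(>|t|)"]),
                method = "lmm"))
  }
  warning("singular mixed-model fit; using patient-cluster permutation test")
  cluster_stat <- function(ev) {
    d <- mean(df$value[ev]) - mean(df$value[!ev])
    if (is.nan(d)) 0 else d
  }
  ev <- df$event == TRUE
  obs <- cluster_stat(ev)
  n <- nrow(df)
  # permute labels within each patient, preserving the cluster structure
  perm <- vapply(seq_len(n_perm), function(i) {
    ev_p <- ev
    for (sp in split(seq_len(n), df$patient))
      ev_p[sp] <- ev[sp][sample(length(sp))]
    cluster_stat(ev_p)
  }, 0)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(estimate = obs, p_value = p, method = "permutation")
}
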