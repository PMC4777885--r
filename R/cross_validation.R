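#' Default parameter grids for the three algorithms
#'
#' RoT: day lag 1-21. MACD: long window 10-50 days in steps of 5, short
#' window 1-10 days, short < long. CUSUM: running-statistics window 10-30
#' days in steps of 5, allowance 0.5-1.5 in steps of 0.2. Grids are ordered
#' from simpler (smaller windows) to more complex settings; optimization
#' breaks ties toward the earlier entry.
#'
#' @param algorithm `"rot"`, `"macd"` or `"cusum"`.
#' @return data frame of candidate parameter settings.
#' @export
default_grid <- function(algorithm = c("rot", "macd", "cusum")) {
  algorithm <- match.arg(algorithm)
  g <- switch(algorithm,
    rot = data.frame(d = 1:21),
    macd = {
      g <- expand.grid(n_short = 1:10, n_long = seq(10, 50, by = 5))
      g <- g[g$n_short < g$n_long, c("n_long", "n_short")]
      g <- g[order(g$n_long, g$n_short), c("n_short", "n_long")]
      g
    },
    cusum = {
      g <- expand.grid(c = seq(0.5, 1.5, by = 0.2),
                       d = seq(10, 30, by = 5))[, c("d", "c")]
      g[order(g$d, g$c), ]
    })
  rownames(g) <- NULL
  g
}

#' Stratified fold assignment for leave-patient-out cross-validation
#'
#' Splits patients into `k` folds balancing both the number of patients and
#' the number of HF-adjudicated events per fold. Event patients are shuffled,
#' ordered by decreasing event count, and dealt greedily to the fold with the
#' fewest events; event-free patients are then dealt to the folds with the
#' fewest patients.
#'
#' @param x a `telealert_cohort` with at least `k` patients.
#' @param k number of folds (default 8).
#' @param seed RNG seed for the shuffles.
#' @return Object of class `fold_assignment`: data frame `patient_id`,
#'   `fold`, with attribute `summary` (patients and events per fold).
#' @export
stratified_folds <- function(x, k = 8, seed = NULL) {
  stopifnot(inherits(x, "telealert_cohort"))
  if (k < 2) stop("k must be >= 2")
  ids <- names(x$records)
  if (length(ids) < k) stop("fewer patients than folds")
  n_events <- vapply(x$records, function(r) sum(r$events$hf_adjudicated), 0L)
  with_seed(seed, {
    fold <- setNames(integer(length(ids)), ids)
    ev_ids <- sample(ids[n_events > 0])
    ev_ids <- ev_ids[order(-n_events[ev_ids])]
    ev_per_fold <- integer(k)
    n_per_fold <- integer(k)
    for (id in ev_ids) {
      f <- order(ev_per_fold, n_per_fold)[1]
      fold[id] <- f
      ev_per_fold[f] <- ev_per_fold[f] + n_events[[id]]
      n_per_fold[f] <- n_per_fold[f] + 1L
    }
    for (id in sample(ids[n_events == 0])) {
      f <- order(n_per_fold, ev_per_fold)[1]
      fold[id] <- f
      n_per_fold[f] <- n_per_fold[f] + 1L
    }
    out <- data.frame(patient_id = ids, fold = unname(fold[ids]))
    attr(out, "summary") <- data.frame(
      fold = seq_len(k), patients = n_per_fold, events = ev_per_fold)
    class(out) <- c("fold_assignment", "data.frame")
    out
  })
}

# Precompute everything that does not depend on the parameter setting:
# per-patient prepared blocks, segmented periods, adherence flags.
cv_context <- function(x, modality, pause_days = 7, min_per_week = 3,
                       adherence_mode = "per_week") {
  stopifnot(inherits(x, "telealert_cohort"))
  direction <- modality_direction(modality)
  ctx <- list(modality = modality, direction = direction,
              pause_days = pause_days, patients = list())
  for (id in names(x$records)) {
    rec <- x$records[[id]]
    s <- rec$series[[modality]]
    if (is.null(s)) next
    per <- segment_periods(rec, pause_days)
    if (nrow(per) == 0) next
    adherent <- vapply(seq_len(nrow(per)), function(i)
      weekly_adherence(s, per$end[i], min_per_week = min_per_week,
                       mode = adherence_mode)$adherent, TRUE)
    per <- per[adherent, , drop = FALSE]
    if (nrow(per) == 0) next
    preps <- prepare_record(rec, modality, pause_days)
    ctx$patients[[id]] <- list(record = rec, periods = per, preps = preps)
  }
  ctx
}

# Index values for one patient under one setting: concatenated over blocks.
patient_index_values <- function(pat, algorithm, setting, direction) {
  dates <- numeric(0); values <- numeric(0)
  for (p in pat$preps) {
    idx <- switch(algorithm,
                  rot = rot_index(p, setting$d),
                  macd = macd_index(p, setting$n_short, setting$n_long),
                  cusum = cusum_index(p, setting$d, setting$c,
                                      direction = direction))
    dates <- c(dates, as.numeric(idx$dates))
    values <- c(values, idx$values)
  }
  list(dates = dates, values = values)
}

# Index values for one patient under every grid setting at once (one column
# per setting). MACD reuses one trailing SMA per distinct window length.
patient_values_matrix <- function(pat, algorithm, grid, direction) {
  blocks <- lapply(pat$preps, function(p) {
    n <- length(p$values)
    m <- matrix(NA_real_, n, nrow(grid))
    if (algorithm == "macd") {
      wins <- sort(unique(c(grid$n_short, grid$n_long)))
      sma <- lapply(wins, function(w) trailing_sma(p$values, w))
      names(sma) <- wins
      for (g in seq_len(nrow(grid)))
        m[, g] <- sma[[as.character(grid$n_short[g])]] -
          sma[[as.character(grid$n_long[g])]]
    } else {
      for (g in seq_len(nrow(grid))) {
        setting <- as.list(grid[g, , drop = FALSE])
        idx <- switch(algorithm,
                      rot = rot_index(p, setting$d),
                      cusum = cusum_index(p, setting$d, setting$c,
                                          direction = direction))
        m[, g] <- idx$values
      }
    }
    list(dates = as.numeric(p$dates), m = m)
  })
  list(dates = do.call(c, lapply(blocks, `[[`, "dates")),
       m = do.call(rbind, lapply(blocks, `[[`, "m")))
}

# Peak of the index inside each adherent period (NA when undefined).
patient_peaks <- function(pat, iv, direction) {
  lo <- findInterval(as.numeric(pat$periods$start) - 0.5, iv$dates) + 1L
  hi <- findInterval(as.numeric(pat$periods$end) + 0.5, iv$dates)
  peak_fun <- if (direction == "increase") max else min
  vapply(seq_len(nrow(pat$periods)), function(i) {
    if (lo[i] > hi[i]) return(NA_real_)
    v <- iv$values[lo[i]:hi[i]]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else peak_fun(v)
  }, 0)
}

#' Labeled period peaks for every grid setting
#'
#' For each candidate parameter setting, computes the output index for every
#' patient, extracts per-period peak values, and pools the eligible
#' (adherent, index-defined) periods of the whole cohort. This table is the
#' input both to parameter optimization on training folds and to out-of-fold
#' evaluation: peaks are computed per patient, so restricting the table to a
#' patient subset is exactly what recomputing on that subset would give.
#'
#' @param x a `telealert_cohort`.
#' @param algorithm `"rot"`, `"macd"` or `"cusum"`.
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @param grid data frame of settings (default [default_grid()]).
#' @param pause_days,min_per_week,adherence_mode see [segment_periods()] and
#'   [weekly_adherence()].
#' @return Object of class `peak_table`: list with `grid`, `direction`,
#'   `modality`, `algorithm`, and `peaks` — one data frame
#'   (`patient_id`, `label`, `peak_index`) per grid row.
#' @export
cohort_peaks <- function(x, algorithm, modality,
                         grid = default_grid(algorithm), pause_days = 7,
                         min_per_week = 3, adherence_mode = "per_week") {
  ctx <- cv_context(x, modality, pause_days, min_per_week, adherence_mode)
  direction <- ctx$direction
  peak_fun <- if (direction == "increase") max else min
  parts <- lapply(ctx$patients, function(pat) {
    vm <- patient_values_matrix(pat, algorithm, grid, direction)
    lo <- findInterval(as.numeric(pat$periods$start) - 0.5, vm$dates) + 1L
    hi <- findInterval(as.numeric(pat$periods$end) + 0.5, vm$dates)
    pk <- matrix(NA_real_, nrow(pat$periods), nrow(grid))
    for (i in seq_len(nrow(pat$periods))) {
      if (lo[i] > hi[i]) next
      sub <- vm$m[lo[i]:hi[i], , drop = FALSE]
      p <- suppressWarnings(apply(sub, 2, peak_fun, na.rm = TRUE))
      p[!is.finite(p)] <- NA_real_
      pk[i, ] <- p
    }
    list(patient_id = pat$record$patient_id, labels = pat$periods$label,
         pk = pk)
  })
  peaks <- lapply(seq_len(nrow(grid)), function(g) {
    rows <- lapply(parts, function(pp) {
      keep <- !is.na(pp$pk[, g])
      if (!any(keep)) return(NULL)
      data.frame(patient_id = pp$patient_id, label = pp$labels[keep],
                 peak_index = pp$pk[keep, g])
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(patient_id = character(), label = character(),
                       peak_index = numeric())
    rownames(df) <- NULL
    df
  })
  structure(list(grid = grid, peaks = peaks, direction = direction,
                 modality = modality, algorithm = algorithm, ctx = ctx),
            class = "peak_table")
}

#' Pick the grid setting maximizing high-specificity partial AUC
#'
#' Scores every setting by the normalized partial AUC of the period-peak ROC
#' restricted to specificity above `spec_min`, over the training patients
#' only, and returns the argmax. Settings whose training periods lack either
#' class are skipped. Ties go to the earlier (simpler) grid entry.
#'
#' @param pt a [cohort_peaks()] table.
#' @param train_ids patient ids forming the training set.
#' @param spec_min specificity bound for the partial AUC (default 0.95).
#' @return List `setting` (one-row data frame), `index` (grid row), `pauc`.
#' @export
optimize_parameters <- function(pt, train_ids, spec_min = 0.95) {
  stopifnot(inherits(pt, "peak_table"))
  scores <- rep(NA_real_, nrow(pt$grid))
  for (g in seq_along(pt$peaks)) {
    df <- pt$peaks[[g]]
    df <- df[df$patient_id %in% train_ids, , drop = FALSE]
    if (!any(df$label == "event") || !any(df$label != "event")) next
    roc <- roc_curve(df, pt$direction)
    scores[g] <- partial_auc(roc, spec_min)
  }
  if (all(is.na(scores)))
    stop("no grid setting yields both period classes on the training folds")
  best <- which(scores >= max(scores, na.rm = TRUE) - 1e-12)[1]
  list(setting = pt$grid[best, , drop = FALSE], index = best,
       pauc = scores[best])
}

#' Normalize output-index values by a training-set scale
#'
#' Divides index values (or period peaks) by a robust scale estimated on
#' training data, so that out-of-fold peaks obtained under different chosen
#' parameters live on one comparable axis and can be pooled into a single
#' ROC curve.
#'
#' @param values numeric.
#' @param scale positive scale (see [training_scale()]).
#' @return `values / scale`.
#' @export
normalize_index <- function(values, scale) {
  if (!is.finite(scale) || scale <= 0)
    stop("training scale must be a positive number")
  values / scale
}

#' Robust scale of an output index on training data
#'
#' Median absolute deviation (scaled by 1.4826 to be consistent with the SD
#' under normality) of all defined training index values; falls back to the
#' standard deviation when the MAD degenerates to zero (e.g. an index that is
#' mostly clamped at zero), and to 1 when even the SD is zero.
#'
#' @param values numeric index values (NAs ignored).
#' @return Positive scale.
#' @export
training_scale <- function(values) {
  v <- values[!is.na(values)]
  s <- stats::mad(v)
  if (!is.finite(s) || s <= 0) s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) s <- 1
  s
}

#' Stratified leave-patient-out cross-validation of an alert algorithm
#'
#' The cohort's patients are split into `k` event-stratified folds. For each
#' fold, algorithm parameters are chosen on the other `k - 1` folds by
#' maximizing the partial AUC at specificity above `spec_min_opt`; the
#' held-out fold's period peaks are then computed under those parameters and
#' normalized by the training-set robust index scale. The held-out folds are
#' recombined into one unbiased ROC curve, on which the operating threshold
#' is chosen as the Youden point with specificity above `spec_min_youden`.
#' Summary metrics, the false-alarm rate per patient-year at the chosen
#' threshold, and a per-fold parameter stability table are reported.
#'
#' @param x a `telealert_cohort` with HF events.
#' @param algorithm `"rot"`, `"macd"` or `"cusum"`.
#' @param modality `"weight_kg"` or `"nitti_log_ohm"`.
#' @param grid candidate settings (default [default_grid()]).
#' @param k number of folds (default 8).
#' @param seed RNG seed for the fold assignment.
#' @param spec_min_opt specificity bound for parameter optimization
#'   (default 0.95).
#' @param spec_min_youden specificity bound for the operating threshold
#'   (default 0.90).
#' @param pause_days,min_per_week,adherence_mode see [segment_periods()] and
#'   [weekly_adherence()].
#' @param max_redeals maximum re-deals of the fold assignment if some fold
#'   leaves a training set without events.
#' @return Object of class `alert_cv`; see [summary.alert_cv()]. Key fields:
#'   `pooled` (out-of-fold normalized peaks with labels and folds), `roc`,
#'   `threshold` (normalized units), `metrics` (sensitivity, specificity,
#'   ppv, npv), `false_alarms`, `fold_table`.
#' @export
cross_validate <- function(x, algorithm = c("rot", "macd", "cusum"),
                           modality, grid = default_grid(algorithm), k = 8,
                           seed = NULL, spec_min_opt = 0.95,
                           spec_min_youden = 0.90, pause_days = 7,
                           min_per_week = 3, adherence_mode = "per_week",
                           max_redeals = 100) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(x, "telealert_cohort"))
  pt <- cohort_peaks(x, algorithm, modality, grid, pause_days,
                     min_per_week, adherence_mode)
  direction <- pt$direction

  # eligible event patients: those contributing at least one event period
  # under at least one setting
  ev_patients <- unique(unlist(lapply(pt$peaks, function(df)
    df$patient_id[df$label == "event"])))
  if (length(ev_patients) == 0)
    stop("cohort has no eligible event-ending periods")

  folds <- NULL
  for (attempt in seq_len(max_redeals)) {
    s <- if (is.null(seed)) NULL else seed + attempt - 1L
    f <- stratified_folds(x, k, s)
    ok <- vapply(seq_len(k), function(ff) {
      train <- f$patient_id[f$fold != ff]
      any(ev_patients %in% train)
    }, TRUE)
    if (all(ok)) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build folds with events in every training set")

  pooled <- list()
  fold_rows <- list()
  chosen <- vector("list", k)
  scale_cache <- new.env(parent = emptyenv())
  for (f in seq_len(k)) {
    train <- folds$patient_id[folds$fold != f]
    test <- folds$patient_id[folds$fold == f]
    best <- optimize_parameters(pt, train, spec_min_opt)
    key <- as.character(best$index)
    if (is.null(scale_cache[[key]])) {
      scale_cache[[key]] <- lapply(pt$ctx$patients, function(pat)
        patient_index_values(pat, algorithm,
                             as.list(pt$grid[best$index, , drop = FALSE]),
                             direction)$values)
    }
    vals <- unlist(scale_cache[[key]][
      names(pt$ctx$patients) %in% train], use.names = FALSE)
    scale <- training_scale(vals)

    train_df <- pt$peaks[[best$index]]
    train_df <- train_df[train_df$patient_id %in% train, , drop = FALSE]
    train_df$peak_index <- normalize_index(train_df$peak_index, scale)
    train_thr <- youden_threshold(roc_curve(train_df, direction),
                                  spec_min_youden)

    test_df <- pt$peaks[[best$index]]
    test_df <- test_df[test_df$patient_id %in% test, , drop = FALSE]
    if (nrow(test_df)) {
      test_df$peak_index <- normalize_index(test_df$peak_index, scale)
      test_df$fold <- f
      pooled[[f]] <- test_df
    }
    chosen[[f]] <- list(setting = best$setting, scale = scale)
    fold_rows[[f]] <- cbind(data.frame(fold = f), best$setting,
                            data.frame(train_pauc = best$pauc,
                                       train_threshold = train_thr$threshold,
                                       scale = scale))
  }
  pooled <- do.call(rbind, pooled)
  rownames(pooled) <- NULL
  roc <- roc_curve(pooled, direction)
  op <- youden_threshold(roc, spec_min_youden)
  conf <- confusion_at_threshold(pooled, op$threshold, direction)

  # false-alarm rate: daily alerts per patient at the pooled threshold,
  # expressed in each fold's raw index units
  alerts <- list()
  fold_of <- setNames(folds$fold, folds$patient_id)
  for (id in names(pt$ctx$patients)) {
    ch <- chosen[[fold_of[[id]]]]
    iv <- patient_index_values(pt$ctx$patients[[id]], algorithm,
                               as.list(ch$setting), direction)
    raw_thr <- op$threshold * ch$scale
    alerts[[id]] <- suppressWarnings(threshold_alerts(
      data.frame(date = as.Date(iv$dates, origin = "1970-01-01"),
                 value = iv$values),
      raw_thr, direction))
  }
  fa <- false_alarm_rate(alerts, x)

  out <- list(algorithm = algorithm, modality = modality,
              direction = direction, k = k, seed = seed, folds = folds,
              fold_table = do.call(rbind, fold_rows), pooled = pooled,
              roc = roc, threshold = op$threshold,
              operating_point = op, confusion = conf$counts,
              metrics = conf$metrics, false_alarms = fa, grid = pt$grid,
              call = match.call())
  class(out) <- "alert_cv"
  out
}

#' @export
print.alert_cv <- function(x, ...) {
  cat(sprintf("Cross-validated alert algorithm: %s on %s (%s direction)\n",
              toupper(x$algorithm), x$modality, x$direction))
  cat(sprintf("  %d folds, %d pooled out-of-fold periods (%d event-ending)\n",
              x$k, nrow(x$pooled), sum(x$pooled$label == "event")))
  m <- x$metrics
  cat(sprintf("  threshold %.3g (normalized): sens %.0f%%, spec %.0f%%, PPV %.1f%%, NPV %.1f%%\n",
              x$threshold, 100 * m[["sensitivity"]],
              100 * m[["specificity"]],
              100 * m[["ppv"]], 100 * m[["npv"]]))
  cat(sprintf("  false alarms: %.2f per patient-year (%d episodes over %.1f years)\n",
              x$false_alarms$rate, x$false_alarms$false_episodes,
              x$false_alarms$patient_years))
  invisible(x)
}

#' Summarize a cross-validated alert algorithm
#'
#' Reports the pooled out-of-fold operating characteristics and a parameter
#' stability table: mean, SD and the individual value of each tuned parameter
#' across folds (the per-fold re-optimization makes parameter variance a
#' direct read-out of how stable the chosen algorithm configuration is).
#'
#' @param object an `alert_cv`.
#' @param ... unused.
#' @return List of class `summary.alert_cv` with `metrics`, `confusion`,
#'   `false_alarm_rate`, `stability` (per-parameter mean/SD + fold values).
#' @export
summary.alert_cv <- function(object, ...) {
  ft <- object$fold_table
  par_cols <- setdiff(names(ft),
                      c("fold", "train_pauc", "train_threshold", "scale"))
  stab <- lapply(c(par_cols, "train_threshold"), function(p) {
    v <- ft[[p]]
    list(parameter = p, mean = mean(v), sd = stats::sd(v), values = v)
  })
  names(stab) <- c(par_cols, "train_threshold")
  out <- list(algorithm = object$algorithm, modality = object$modality,
              metrics = object$metrics, confusion = object$confusion,
              threshold = object$threshold,
              false_alarm_rate = object$false_alarms$rate,
              stability = stab, k = object$k)
  class(out) <- "summary.alert_cv"
  out
}

#' @export
print.summary.alert_cv <- function(x, ...) {
  cat(sprintf("%s / %s — pooled out-of-fold performance (%d-fold CV)\n",
              toupper(x$algorithm), x$modality, x$k))
  m <- x$metrics
  cat(sprintf("  sensitivity %.0f%%  specificity %.0f%%  PPV %.1f%%  NPV %.1f%%\n",
              100 * m[["sensitivity"]], 100 * m[["specificity"]],
              100 * m[["ppv"]], 100 * m[["npv"]]))
  cat(sprintf("  false alarms/patient-year %.2f\n", x$false_alarm_rate))
  cat("  parameter stability across folds (mean (SD); fold values):\n")
  for (s in x$stability) {
    cat(sprintf("    %-16s %.3g (%.3g); %s\n", s$parameter, s$mean,
                if (is.na(s$sd)) 0 else s$sd,
                paste(signif(s$values, 3), collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.alert_cv <- function(object, ...) {
  ft <- object$fold_table
  par_cols <- setdiff(names(ft),
                      c("fold", "train_pauc", "train_threshold", "scale"))
  out <- ft[, c("fold", par_cols, "train_threshold")]
  attr(out, "pooled_threshold") <- object$threshold
  out
}

#' Plot the pooled cross-validated ROC curve
#'
#' @param x an `alert_cv`.
#' @param spec_range specificity range shown (default the high-specificity
#'   region 0.9-1 used for threshold selection).
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.alert_cv <- function(x, spec_range = c(0.9, 1), ...) {
  r <- x$roc[order(x$roc$specificity), ]
  plot.default(1 - r$specificity, r$sensitivity, type = "s",
               xlim = 1 - rev(spec_range), ylim = c(0, 1),
               xlab = "1 - specificity", ylab = "sensitivity",
               main = sprintf("%s on %s: pooled out-of-fold ROC",
                              toupper(x$algorithm), x$modality), ...)
  abline(0, 1, lty = 3, col = "red")
  op <- x$operating_point
  points(1 - op$specificity, op$sensitivity, pch = 19)
  legend("bottomright", bty = "n",
         legend = sprintf("Youden point: sens %.0f%%, spec %.0f%%",
                          100 * op$sensitivity, 100 * op$specificity))
  invisible(x)
}
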