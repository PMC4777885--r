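test_that("a 28-day event-free record gives two periods, none discarded", {
  r <- flat_record(n_days = 28)
  per <- segment_periods(r)
  expect_equal(nrow(per), 2)
  expect_equal(per$start[1], r$monitoring_start)
  expect_equal(per$end[2], r$monitoring_end)
  expect_true(all(per$label == "non_event"))
})

test_that("event periods are tiled backward from the admission day", {
  # monitoring days 0..59, admission on day 20: one event window days 7-20,
  # days 0-6 discarded at the block start
  r <- flat_record(n_days = 60)
  adm <- r$monitoring_start + 20
  r <- inject_event(r, adm, prodrome_days = 5)
  per <- segment_periods(r)
  evp <- per[per$label == "event", ]
  expect_equal(nrow(evp), 1)
  expect_equal(evp$end, adm)
  expect_equal(evp$start, adm - 13)
  expect_false(any(per$start < adm - 13 & per$label == "non_event" &
                     per$end <= adm))  # days 0-6 are not covered
  # post-pause block: days 28..59 -> 2 forward-tiled non-event windows
  post <- per[per$start > adm, ]
  expect_equal(nrow(post), 2)
  expect_equal(post$start[1], adm + 8)
})

test_that("day bookkeeping is conserved over random event placements", {
  set.seed(21)
  for (i in 1:40) {
    n_days <- sample(30:200, 1)
    r <- flat_record(n_days = n_days)
    n_ev <- sample(0:2, 1)
    adm <- sort(sample(10:(n_days - 1), n_ev))
    adm <- adm[c(TRUE, diff(adm) > 25)[seq_along(adm)]]
    for (a in adm)
      r <- suppressWarnings(inject_event(r, r$monitoring_start + a))
    per <- segment_periods(r, pause_days = 7)
    blocks <- monitoring_blocks(r, pause_days = 7)
    covered <- 14 * nrow(per)
    block_days <- sum(as.numeric(blocks$end - blocks$start) + 1)
    discarded <- block_days - covered
    pauses <- sum(vapply(r$events$admission_date, function(a)
      min(7, as.numeric(r$monitoring_end - a)), 0))
    total <- as.numeric(r$monitoring_end - r$monitoring_start) + 1
    expect_gte(discarded, 0)
    expect_equal(covered + discarded + pauses, total)
  }
})

test_that("non-HF hospitalizations end no period but pause monitoring", {
  r <- flat_record(n_days = 90)
  r <- inject_event(r, r$monitoring_start + 41, hf_adjudicated = FALSE)
  per <- segment_periods(r)
  expect_true(all(per$label == "non_event"))
  # block before the admission is tiled forward: 42 days -> 3 windows
  expect_equal(sum(per$end <= r$monitoring_start + 41), 3)
})

test_that("records shorter than 14 days yield no periods", {
  r <- flat_record(n_days = 10)
  expect_equal(nrow(segment_periods(r)), 0)
})

test_that("non-adherent periods are excluded, including event windows", {
  r <- flat_record(n_days = 56)
  adm <- r$monitoring_start + 41
  r <- inject_event(r, adm)
  # thin the weight series to 2 observations/week in the event window
  s <- r$series$weight_kg
  keep <- !(s$dates >= adm - 13 & s$dates <= adm) |
    (as.numeric(s$dates - adm) %% 4 == 0)
  r$series$weight_kg <- measurement_series("P1", "weight_kg",
                                           s$dates[keep], s$values[keep])
  per <- segment_periods(r)
  idx <- record_index(r, "rot", "weight_kg", list(d = 3))
  lab <- label_periods(per, idx, r$series$weight_kg, "increase")
  expect_false(any(lab$label == "event"))  # excluded, not counted as missed

  # fully adherent nitti series keeps its event window
  idx_n <- record_index(r, "rot", "nitti_log_ohm", list(d = 3))
  lab_n <- label_periods(per, idx_n, r$series$nitti_log_ohm, "decrease")
  expect_equal(sum(lab_n$label == "event"), 1)
})

test_that("periods with no defined index value are dropped (warm-up)", {
  r <- flat_record(n_days = 28)
  per <- segment_periods(r)
  idx <- record_index(r, "macd", "weight_kg", list(n_short = 2, n_long = 20))
  lab <- label_periods(per, idx, r$series$weight_kg, "increase")
  expect_equal(nrow(lab), 1)  # the first window is all warm-up
})

test_that("confusion counts match brute-force enumeration", {
  set.seed(33)
  for (i in 1:10) {
    per <- fake_periods(rnorm(4), rnorm(16))
    thr <- rnorm(1)
    for (dir in c("increase", "decrease")) {
      got <- confusion_at_threshold(per, thr, dir)
      cross <- if (dir == "increase") per$peak_index > thr
               else per$peak_index < thr
      expect_equal(unname(got$counts),
                   c(sum(cross & per$label == "event"),
                     sum(cross & per$label != "event"),
                     sum(!cross & per$label != "event"),
                     sum(!cross & per$label == "event")))
      expect_equal(sum(got$counts[c("TP", "FN")]),
                   sum(per$label == "event"))
    }
  }
})

test_that("degenerate thresholds give the trivial operating points", {
  per <- fake_periods(c(1, 2), c(-1, 0, 0.5))
  all_below <- confusion_at_threshold(per, 10, "increase")
  expect_equal(unname(all_below$counts), c(0, 0, 3, 2))
  expect_equal(all_below$metrics[["specificity"]], 1)
  expect_true(is.na(all_below$metrics[["ppv"]]))
  all_alert <- confusion_at_threshold(per, -Inf, "increase")
  expect_equal(all_alert$metrics[["sensitivity"]], 1)
  expect_equal(all_alert$metrics[["specificity"]], 0)
})

test_that("ROC endpoints and monotonicity hold; separable data give AUC 1", {
  per <- fake_periods(c(5, 6, 7), c(1, 2, 3))
  roc <- roc_curve(per, "increase")
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 0))
  expect_true(any(roc$sensitivity == 0 & roc$specificity == 1))
  ord <- order(roc$specificity)
  expect_true(all(diff(roc$sensitivity[ord]) <= 0))
  expect_equal(partial_auc(roc, 0), 1)
  expect_equal(partial_auc(roc, 0.95), 1)

  # identical score distributions: chance level
  per2 <- fake_periods(c(1, 2), c(1, 2))
  expect_equal(partial_auc(roc_curve(per2, "increase"), 0), 0.5)
  expect_error(roc_curve(fake_periods(numeric(), 1:3), "increase"),
               "at least one")
})

test_that("ROC and partial AUC match exhaustive enumeration", {
  set.seed(44)
  for (i in 1:15) {
    per <- fake_periods(rnorm(3), rnorm(12))
    dir <- sample(c("increase", "decrease"), 1)
    roc <- roc_curve(per, dir)
    # oracle: enumerate every threshold, compute rates by counting
    for (j in seq_len(nrow(roc))) {
      th <- roc$threshold[j]
      cross <- if (dir == "increase") per$peak_index > th
               else per$peak_index < th
      expect_equal(roc$sensitivity[j],
                   sum(cross & per$label == "event") /
                     sum(per$label == "event"))
      expect_equal(roc$specificity[j],
                   sum(!cross & per$label != "event") /
                     sum(per$label != "event"))
    }
  }
})

test_that("the Youden point matches constrained exhaustive search", {
  set.seed(55)
  for (i in 1:15) {
    per <- fake_periods(rnorm(4, 1), rnorm(20))
    roc <- roc_curve(per, "increase")
    got <- youden_threshold(roc, 0.75)
    ok <- roc$specificity > 0.75
    j <- roc$sensitivity + roc$specificity - 1
    expect_equal(got$youden, max(j[ok]))
    # tie-break toward higher specificity
    cand <- which(ok & j == max(j[ok]))
    expect_equal(got$specificity, max(roc$specificity[cand]))
  }
})

test_that("youden_threshold warns when the constraint cannot be met", {
  per <- fake_periods(c(1, 1), c(1, 1))
  roc <- roc_curve(per, "increase")
  got <- youden_threshold(roc, 0.90)
  expect_equal(got$youden, 0)
  expect_warning(
    youden_threshold(structure(roc[roc$specificity < 0.5, ],
                               class = class(roc)), 0.90),
    "most specific")
})

test_that("separable scores give a threshold between the classes with J = 1", {
  per <- fake_periods(c(10, 11), c(1, 2, 3))
  got <- youden_threshold(roc_curve(per, "increase"), 0.5)
  expect_equal(got$youden, 1)
  expect_gte(got$threshold, 3)
  expect_lt(got$threshold, 10)
})

test_that("false alarms per patient-year merge consecutive alert days", {
  start <- as.Date("2020-01-01")
  mk_rec <- function(id, n) {
    days <- start + seq_len(n) - 1
    patient_record(id, start, start + n - 1, series = list(
      measurement_series(id, "weight_kg", days, rep(80, n))))
  }
  co <- cohort(list(mk_rec("A", 731), mk_rec("B", 730)))  # 4 patient-years
  no_alerts <- list(A = data.frame(date = start, alert = FALSE))
  expect_equal(false_alarm_rate(no_alerts, co)$rate, 0)

  # two separated false episodes: days 10-12 and 100
  alerts <- list(A = data.frame(date = start + c(9, 10, 11, 99),
                                alert = TRUE))
  fa <- false_alarm_rate(alerts, co)
  expect_equal(fa$false_episodes, 2)
  expect_equal(fa$rate, 0.5)
})

test_that("a five-week alert is one episode but several window false positives", {
  r <- flat_record(n_days = 70)
  co <- cohort(list(r))
  days <- r$monitoring_start + 10:44  # 35 consecutive alert days
  alerts <- list(P1 = data.frame(date = days, alert = TRUE))
  fa <- false_alarm_rate(alerts, co)
  expect_equal(fa$episodes, 1)
  expect_equal(fa$false_episodes, 1)
  # the same alert crosses >= 3 two-week windows
  per <- segment_periods(r)
  hit <- vapply(seq_len(nrow(per)), function(i)
    any(days >= per$start[i] & days <= per$end[i]), TRUE)
  expect_gte(sum(hit), 3)
})

test_that("an episode followed by an HF admission within 14 days is not false", {
  r <- flat_record(n_days = 80)
  r <- inject_event(r, r$monitoring_start + 49)
  co <- cohort(list(r))
  alerts <- list(P1 = data.frame(date = r$monitoring_start + c(39, 40),
                                 alert = TRUE))
  fa <- false_alarm_rate(alerts, co)
  expect_equal(fa$episodes, 1)
  expect_equal(fa$false_episodes, 0)
})

test_that("compare_period_means recovers an injected shift and handles degeneracy", {
  set.seed(66)
  n_pat <- 40
  pid <- rep(seq_len(n_pat), each = 8)
  base <- rnorm(n_pat, 3.4, 0.3)[pid]
  lab <- rep("non_event", length(pid))
  lab[seq(1, length(pid), by = 8)] <- "event"
  val <- base + rnorm(length(pid), 0, 0.05) - 0.4 * (lab == "event")
  fit <- compare_period_means(val, lab, pid)
  expect_equal(fit$estimate, -0.4, tolerance = 0.05)
  expect_lt(fit$p_value, 0.001)

  same <- compare_period_means(rep(1, 20), rep(c("event", "non_event"), 10),
                               rep(1:2, each = 10))
  expect_equal(same$estimate, 0)
})
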