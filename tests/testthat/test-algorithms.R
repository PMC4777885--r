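test_that("all three indices are identically zero on a constant series", {
  p <- prepared_from_values(rep(5, 60))
  expect_equal(rot_index(p, 3)$values[4:60], rep(0, 57))
  expect_equal(macd_index(p, 5, 20)$values[20:60], rep(0, 41))
  expect_equal(cusum_index(p, 10, 0.5, "decrease")$values[11:60], rep(0, 50))
  expect_equal(cusum_index(p, 10, 0.5, "increase")$values[11:60], rep(0, 50))
})

test_that("warm-up lengths match the definitions", {
  p <- prepared_from_values(rnorm(40))
  expect_equal(which(!is.na(rot_index(p, 7)$values))[1], 8)
  expect_equal(which(!is.na(macd_index(p, 3, 15)$values))[1], 15)
  expect_equal(which(!is.na(cusum_index(p, 10, 1, "increase")$values))[1], 11)
})

test_that("RoT on a steady rise crosses the ESC two-kilogram rule", {
  p <- prepared_from_values(80 + 0.7 * (0:29), modality = "weight_kg")
  idx <- rot_index(p, 3)
  expect_equal(idx$values[10], 2.1)
  expect_gt(idx$values[10], 2)  # ESC: >2 kg in 3 days
})

test_that("MACD on a linear ramp converges to slope * (n_long - n_short) / 2", {
  for (s in c(0.1, 0.7)) {
    p <- prepared_from_values(s * (1:80))
    idx <- macd_index(p, 5, 20)
    expect_equal(idx$values[30:80], rep(s * (20 - 5) / 2, 51),
                 tolerance = 1e-9)
  }
})

test_that("CUSUM accumulates roughly one unit per day on a sustained shift", {
  # steady noise sd 1, then a level drop of k*sigma per day with k - c = 1
  set.seed(3)
  base <- rnorm(40, 0, 1)
  c_allow <- 0.75
  # after day 40 the value drops so that z ~ -(1 + c) each day
  p <- prepared_from_values(c(base, base[40] - cumsum(rep(1.75, 20))))
  idx <- cusum_index(p, 20, c_allow, "decrease")
  post <- idx$values[41:60]
  expect_lt(post[10], -5)
  expect_lt(min(post), -7.8)  # crosses the deep-alert threshold
})

test_that("indices equal their brute-force oracles on random series", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(100)
    p <- prepared_from_values(x)
    d <- sample(1:21, 1)
    expect_equal(rot_index(p, d)$values, oracle_rot(x, d))
    ns <- sample(1:9, 1); nl <- sample(10:50, 1)
    expect_equal(macd_index(p, ns, nl)$values, oracle_macd(x, ns, nl))
    dd <- sample(2:30, 1); cc <- runif(1, 0, 2)
    dir <- sample(c("increase", "decrease"), 1)
    expect_equal(cusum_index(p, dd, cc, dir)$values,
                 oracle_cusum(x, dd, cc, dir))
  }
})

test_that("translation invariance holds for all indices, scale invariance for CUSUM", {
  set.seed(5)
  x <- rnorm(80, 10)
  p <- prepared_from_values(x)
  p_shift <- prepared_from_values(x + 123.4)
  p_scaled <- prepared_from_values(x * 3.7)
  expect_equal(rot_index(p, 5)$values, rot_index(p_shift, 5)$values)
  expect_equal(macd_index(p, 4, 18)$values, macd_index(p_shift, 4, 18)$values)
  expect_equal(cusum_index(p, 12, 0.9, "decrease")$values,
               cusum_index(p_shift, 12, 0.9, "decrease")$values)
  # standardization makes CUSUM scale-free; RoT/MACD scale linearly
  expect_equal(cusum_index(p, 12, 0.9, "decrease")$values,
               cusum_index(p_scaled, 12, 0.9, "decrease")$values,
               tolerance = 1e-8)
  expect_equal(rot_index(p_scaled, 5)$values, 3.7 * rot_index(p, 5)$values)
  expect_equal(macd_index(p_scaled, 4, 18)$values,
               3.7 * macd_index(p, 4, 18)$values)
})

test_that("CUSUM is one-sided", {
  set.seed(9)
  for (i in 1:10) {
    p <- prepared_from_values(rnorm(60))
    dec <- cusum_index(p, 10, 0.5, "decrease")$values
    inc <- cusum_index(p, 10, 0.5, "increase")$values
    expect_true(all(dec <= 0, na.rm = TRUE))
    expect_true(all(inc >= 0, na.rm = TRUE))
  }
})

test_that("index values are causal: truncating future data changes nothing", {
  set.seed(13)
  for (i in 1:5) {
    s <- random_series(50, p_obs = 0.7)
    full <- prepare_series(s)
    for (t_i in unique(pmin(c(20, 35, length(s$dates)), length(s$dates)))) {
      t <- s$dates[t_i]
      keep <- s$dates <= t
      trunc <- prepare_series(measurement_series(s$patient_id, s$modality,
                                                 s$dates[keep],
                                                 s$values[keep]))
      n <- length(trunc$dates)
      expect_equal(rot_index(trunc, 4)$values[n],
                   rot_index(full, 4)$values[n])
      expect_equal(macd_index(trunc, 3, 12)$values[n],
                   macd_index(full, 3, 12)$values[n])
      expect_equal(cusum_index(trunc, 8, 0.7, "decrease")$values[n],
                   cusum_index(full, 8, 0.7, "decrease")$values[n])
    }
  }
})

test_that("parameter validation errors fire", {
  p <- prepared_from_values(rnorm(30))
  expect_error(rot_index(p, 0), ">= 1")
  expect_error(macd_index(p, 10, 10), "smaller")
  expect_error(cusum_index(p, 1, 0.5), ">= 2")
  expect_error(cusum_index(p, 10, -0.1), ">= 0")
})

test_that("threshold alerts fire only beyond the threshold in direction", {
  p <- prepared_from_values(rep(0, 30))
  idx <- macd_index(p, 2, 10)
  expect_false(any(threshold_alerts(idx, 0.62, "increase")$alert))
  a <- suppressWarnings(threshold_alerts(idx, Inf, "decrease"))
  expect_equal(sum(a$alert), sum(!is.na(idx$values)))  # every defined day
  expect_warning(threshold_alerts(idx, -1, "increase"), "negative")
  expect_warning(threshold_alerts(idx, 1, "decrease"), "positive")
})

test_that("guideline presets cover the published rules and convert pounds", {
  rules <- guideline_rules()
  expect_length(rules, 13)
  expect_equal(rules$hfsa_2lb_1d$clauses$threshold_kg, 0.9)
  expect_equal(rules$esc_2kg_3d$clauses$threshold_kg, 2)
  expect_equal(rules$zhang_macd$type, "macd")
  expect_equal(rules$zhang_macd$clauses$n_long, 80)

  # a 1.0 kg one-day jump beats the 0.9 kg HFSA rule but not ESC 2 kg/3 d
  p <- prepared_from_values(c(rep(80, 10), rep(81, 10)),
                            modality = "weight_kg")
  expect_true(any(guideline_alerts(p, "hfsa_2lb_1d")$alert))
  expect_false(any(guideline_alerts(p, "esc_2kg_3d")$alert))

  # flat series never fires any preset
  flat <- prepared_from_values(rep(80, 120), modality = "weight_kg")
  for (nm in names(rules))
    expect_false(any(guideline_alerts(flat, nm)$alert), label = nm)

  # slow ramp 0.3 kg/day: weekly rule fires before any 1-day rule
  ramp <- prepared_from_values(80 + 0.3 * (0:60), modality = "weight_kg")
  wk <- guideline_alerts(ramp, "hfsa_4lb_1wk")
  d1 <- guideline_alerts(ramp, "hfsa_2lb_1d")
  expect_true(any(wk$alert))
  expect_false(any(d1$alert))  # 0.3 kg/day never exceeds 0.9 kg in one day
})

test_that("OR-combined clauses fire on either branch", {
  # 1.0 kg in 1 day exceeds 2 lbs (0.9 kg); 3-day change 1.0 < 1.35 kg
  p <- prepared_from_values(c(rep(80, 10), rep(81, 20)),
                            modality = "weight_kg")
  a <- guideline_alerts(p, "abraham_2lb1d_3lb3d")
  expect_true(any(a$alert))
  # neither branch: 1.0 kg over 3 days only
  p2 <- prepared_from_values(c(rep(80, 10), 80 + (1:3) / 3, rep(81, 10)),
                             modality = "weight_kg")
  expect_false(any(guideline_alerts(p2, "abraham_3lb1d_5lb3d")$alert))
})

test_that("optimal presets table is well-formed", {
  op <- optimal_presets()
  expect_equal(nrow(op), 6)
  expect_true(all(op$threshold[op$direction == "decrease"] < 0))
  expect_true(all(op$threshold[op$direction == "increase"] > 0))
})
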