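# detection, staging and eGFR engine

test_that("rolling minimum uses the half-open trailing window", {
  s <- lab_series(c(0, 24, 60), c(1.0, 0.8, 1.3))
  expect_equal(rolling_min(s, t = 60, window = 168), 0.8)
  # single measurement at t is its own window minimum
  expect_equal(rolling_min(lab_series(5, 1.1), t = 5, window = 48), 1.1)
  # a measurement exactly `window` hours before t is excluded
  s2 <- lab_series(c(0, 48), c(0.6, 1.0))
  expect_equal(rolling_min(s2, t = 48, window = 48), 1.0)
  expect_true(is.na(rolling_min(s2, t = 300, window = 48)))
})

test_that("detection fires exactly at the printed criterion boundaries", {
  ep <- detect_aki(lab_series(c(0, 36), c(0.8, 1.1)))   # delta = 0.3 in 48 h
  expect_equal(ep$onset_time, 36)
  expect_equal(ep$criterion, "delta048")
  expect_equal(ep$baseline_scr, 0.8)
  expect_equal(ep$scr_at_aki, 1.1)

  ep2 <- detect_aki(lab_series(c(0, 144), c(0.8, 1.2))) # ratio exactly 1.5
  expect_equal(ep2$criterion, "ratio7d")
  expect_equal(ep2$onset_time, 144)

  expect_null(detect_aki(lab_series(c(0, 36), c(0.8, 1.05))))
  # 0.3 rise but outside the 48 h window, ratio below 1.5
  expect_null(detect_aki(lab_series(c(0, 100), c(1.2, 1.5))))
})

test_that("earliest qualifying measurement defines onset and baseline", {
  s <- lab_series(c(0, 24, 50, 80), c(1.0, 0.8, 1.15, 2.0))
  ep <- detect_aki(s)
  expect_equal(ep$onset_time, 50)  # 1.15 - 0.8 >= 0.3 at t = 50
  expect_equal(ep$baseline_scr, 0.8)
  expect_true(ep$scr_at_aki >= ep$baseline_scr)
})

test_that("staging follows the ratio bands, KRT and high-creatinine rules", {
  s <- lab_series(c(0, 24, 48, 72), c(0.8, 1.2, 1.6, 1.52))
  ep <- detect_aki(s)
  mk <- function(scr_t) {
    ss <- lab_series(c(0, 24, 48), c(0.8, 1.2, scr_t))
    list(ss, detect_aki(ss))
  }
  # ratio 2.0 -> stage 2; ratio 1.9 -> stage 1; ratio 3.0 -> stage 3
  x <- mk(1.6);  expect_equal(stage_at(x[[1]], x[[2]], 48), 2L)
  x <- mk(1.52); expect_equal(stage_at(x[[1]], x[[2]], 48), 1L)
  x <- mk(2.4);  expect_equal(stage_at(x[[1]], x[[2]], 48), 3L)
  # KRT forces stage 3 at any ratio
  expect_equal(stage_at(s, ep, 24, krt_started = TRUE), 3L)
  # creatinine value >= 4.0 mg/dL is stage 3 under the default rule, but not
  # under the literal increase-of-4.0 reading
  hs <- lab_series(c(0, 24, 48), c(2.6, 3.0, 4.1))
  hep <- detect_aki(hs)
  expect_equal(stage_at(hs, hep, 48), 3L)
  expect_equal(stage_at(hs, hep, 48, scr4_rule = "increase"), 1L)
  expect_error(stage_at(s, ep, 10), "onset")
})

test_that("highest stage is the running maximum and dialysis forces 3", {
  s <- lab_series(c(0, 24, 48, 72, 96), c(0.8, 1.2, 1.7, 1.3, 1.1))
  ep <- detect_aki(s)
  expect_equal(highest_stage(s, ep, 96), 2L)  # peak ratio 1.7/0.8 = 2.1
  expect_equal(highest_stage(s, ep, 24), 1L)
  dial <- data.frame(kind = "dialysis_start", time = 60)
  expect_equal(highest_stage(s, ep, 96, events = dial), 3L)
  expect_equal(highest_stage(s, ep, 40, events = dial), 1L)  # not yet started
})

test_that("CKD-EPI eGFR matches hand-computed values and is monotone", {
  # frozen from an independent evaluation of the published 2009 equation
  expect_equal(egfr(1.0, 60, "male"), 81.44290, tolerance = 1e-6)
  expect_equal(egfr(1.0, 60, "female"), 61.18505, tolerance = 1e-6)
  # with SCr above both kappas the sex ratio is 1.018 * (0.9/0.7)^-1.209
  expect_equal(egfr(1.2, 60, "female") / egfr(1.2, 60, "male"),
               1.018 * (0.9 / 0.7)^-1.209, tolerance = 1e-10)
  # strictly decreasing in creatinine and in age
  scr <- seq(0.4, 6, by = 0.2)
  expect_true(all(diff(egfr(scr, 50, "male")) < 0))
  expect_true(all(diff(egfr(scr, 50, "female")) < 0))
  ages <- seq(18, 90, by = 4)
  expect_true(all(diff(egfr(1.3, ages, "male")) < 0))
  expect_lt(egfr(2.0, 60, "male"), egfr(1.0, 60, "male"))
  expect_error(egfr(0, 60, "male"), "positive")
  expect_error(egfr(1, 12, "male"), "18")
  # race and 2021 variants shift as published
  expect_equal(egfr(1.0, 60, "male", variant = "ckdepi2009_race", black = TRUE),
               egfr(1.0, 60, "male") * 1.159)
  expect_gt(egfr(1.0, 60, "male", variant = "ckdepi2021"),
            egfr(1.0, 60, "male"))
})

test_that("detection agrees with a brute-force pairwise oracle", {
  set.seed(401)
  for (rep in 1:200) {
    s <- random_series(sample(2:12, 1))
    ep <- detect_aki(s)
    expect_identical(if (is.null(ep)) NA_real_ else ep$onset_time,
                     oracle_detect(s))
  }
})

test_that("detection is prefix-monotone: later data never change an onset", {
  set.seed(402)
  for (rep in 1:50) {
    s <- random_series(10)
    ep_full <- detect_aki(s)
    for (k in 2:9) {
      ep_k <- detect_aki(lab_series(s$time[1:k], s$scr[1:k]))
      if (!is.null(ep_k)) {
        expect_equal(ep_full$onset_time, ep_k$onset_time)
        break
      }
    }
  }
})

test_that("unit round-trip through umol/L preserves detection decisions", {
  set.seed(403)
  for (rep in 1:50) {
    s <- random_series(8)
    s_rt <- lab_series(s$time, s$scr * 88.4 / 88.4)
    ep <- detect_aki(s); ep_rt <- detect_aki(s_rt)
    expect_identical(is.null(ep), is.null(ep_rt))
    if (!is.null(ep)) expect_equal(ep$onset_time, ep_rt$onset_time)
  }
})

test_that("stage_at is nondecreasing in the current creatinine", {
  base <- lab_series(c(0, 24), c(0.8, 1.2))
  ep <- detect_aki(base)
  stages <- vapply(seq(1.2, 4.4, by = 0.2), function(v) {
    s <- lab_series(c(0, 24, 48), c(0.8, 1.2, v))
    stage_at(s, detect_aki(s), 48)
  }, integer(1))
  expect_true(all(diff(stages) >= 0))
})
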