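# trial outcome definitions

demo60 <- demographics(60, "male")

aki_case <- function(scrs = c(0.8, 1.2, 1.6, 1.3, 1.0),
                     times = c(0, 24, 48, 96, 140)) {
  s <- lab_series(times, scrs)
  list(series = s, episode = detect_aki(s))
}

test_that("death within 7 days imputes eGFR 0 so the change equals eGFR at AKI", {
  x <- aki_case()
  po <- primary_outcome(x$series, demo60, randomization_time = 24,
                        death_time = 24 + 72)
  expect_true(po$died_within_7d)
  expect_identical(po$lowest_egfr_7d, 0)
  expect_equal(po$max_abs_egfr_change, po$egfr_at_aki)
  expect_equal(po$max_rel_egfr_change, 1)
})

test_that("improving kidney function gives a negative change", {
  s <- lab_series(c(0, 24, 60, 100), c(0.8, 1.2, 0.9, 0.7))
  po <- primary_outcome(s, demo60, randomization_time = 24)
  expect_lt(po$max_abs_egfr_change, 0)
  # lowest follow-up eGFR comes from the highest follow-up creatinine (0.9)
  expect_equal(po$lowest_egfr_7d, egfr(0.9, 60, "male"))
})

test_that("flat follow-up gives zero change; none at all gives NA", {
  s <- lab_series(c(0, 24, 60), c(0.8, 1.2, 1.2))
  po <- primary_outcome(s, demo60, 24)
  expect_equal(po$max_abs_egfr_change, 0)
  expect_equal(po$max_rel_egfr_change, 0)

  s2 <- lab_series(c(0, 24), c(0.8, 1.2))
  po2 <- primary_outcome(s2, demo60, 24)
  expect_true(is.na(po2$max_abs_egfr_change))
  expect_true(is.na(po2$max_rel_egfr_change))
})

test_that("windowed death flags respect half-open windows and implications", {
  x <- aki_case()
  ev <- data.frame(patient_id = "P", time = 24 + 10 * 24, kind = "death",
                   value = NA_real_)
  so <- secondary_outcomes(x$series, x$episode, ev, demo60,
                           randomization_time = 24, discharge_time = 24 + 10 * 24)
  expect_false(so$death_7d)
  expect_true(so$death_28d)
  expect_true(so$death_90d)
  expect_true(so$in_hospital_death)
  expect_false(so$recovery_at_discharge)
})

test_that("progression records the strictly higher subsequent stage", {
  s <- lab_series(c(0, 24, 48, 96), c(0.8, 1.2, 1.3, 2.6))  # 3.25x at 96 h
  ep <- detect_aki(s)
  so <- secondary_outcomes(s, ep, NULL, demo60, 24, 200)
  expect_true(so$aki_progression)
  expect_identical(so$stage_from, 1L)
  expect_identical(so$stage_to, 3L)
  expect_identical(so$highest_stage, 3L)
  # no progression when the stage never rises
  s2 <- lab_series(c(0, 24, 48), c(0.8, 1.2, 1.1))
  so2 <- secondary_outcomes(s2, detect_aki(s2), NULL, demo60, 24, 200)
  expect_false(so2$aki_progression)
  expect_true(is.na(so2$stage_to))
})

test_that("dialysis on day 3 sets both dialysis flags and stage 3", {
  x <- aki_case()
  ev <- data.frame(patient_id = "P", time = 24 + 72, kind = "dialysis_start",
                   value = NA_real_)
  so <- secondary_outcomes(x$series, x$episode, ev, demo60, 24, 300)
  expect_true(so$dialysis_7d)
  expect_true(so$in_hospital_dialysis)
  expect_identical(so$highest_stage, 3L)
  expect_false(so$recovery_at_discharge)  # not dialysis-free
})

test_that("care flags respect the 2/3/7-day windows", {
  ev <- data.frame(patient_id = "P",
                   time = c(50, 100, 30, 30, 47.9),
                   kind = c("nsaid", "vancomycin", "iv_fluids", "hemoglobin",
                            "urinalysis"),
                   value = c(NA, NA, NA, 9.0, NA))
  co <- care_outcomes(ev, randomization_time = 0, discharge_time = 400)
  expect_true(co$nsaid_3d)        # 50 h < 72 h
  expect_true(co$nsaid_7d)
  expect_false(co$vancomycin_3d)  # 100 h only
  expect_true(co$vancomycin_7d)
  expect_true(co$iv_fluids_2d)
  expect_true(co$urinalysis_2d)
  # hemoglobin exactly 9.0 g/dL does not count as corrected ("over 9.0")
  expect_false(co$anemia_corrected_2d)
  co2 <- care_outcomes(data.frame(patient_id = "P", time = 30,
                                  kind = "hemoglobin", value = 9.01), 0, 400)
  expect_true(co2$anemia_corrected_2d)
  # every 3-day exposure implies the 7-day exposure
  for (tox in c("contrast", "aminoglycoside", "vancomycin", "chemotherapy",
                "nsaid", "acei_arb")) {
    expect_true(!co[[paste0(tox, "_3d")]] || co[[paste0(tox, "_7d")]])
  }
  expect_warning(care_outcomes(data.frame(patient_id = "P", time = 10,
                                          kind = "acupuncture", value = NA), 0),
                 "acupuncture")
})

test_that("extending a window horizon never turns a flag off", {
  set.seed(77)
  kinds <- c("nsaid", "contrast", "iv_fluids", "urinalysis")
  for (rep in 1:25) {
    ev <- data.frame(patient_id = "P",
                     time = runif(6, 0, 300),
                     kind = sample(kinds, 6, replace = TRUE),
                     value = NA_real_)
    co3 <- care_outcomes(ev, 0, 200)
    for (tox in c("nsaid", "contrast")) {
      expect_true(!co3[[paste0(tox, "_3d")]] || co3[[paste0(tox, "_7d")]])
    }
  }
})

test_that("recovery at discharge follows the documented default rule", {
  x <- aki_case()  # last SCr 1.0 < 1.5 x 0.8
  expect_true(recovery_at_discharge(x$series, x$episode, 140, NULL))
  # last SCr 1.6 x baseline fails the default ratio rule
  s <- lab_series(c(0, 24, 60), c(0.8, 1.2, 1.28))
  expect_false(recovery_at_discharge(s, detect_aki(s), 60, NULL))
  # in-hospital death can never be recovery
  ev <- data.frame(patient_id = "P", time = 100, kind = "death", value = NA_real_)
  expect_false(recovery_at_discharge(x$series, x$episode, 140, ev))
})
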