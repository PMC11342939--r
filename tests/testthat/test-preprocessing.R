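make_patients <- function(n, age_bin = "[40,65)", height_bin = "[155,190)",
                          weight_bin = "[50,80)", bmi_bin = "[18,35)",
                          mv_hours = 100) {
  data.frame(patient_id = sprintf("T%03d", seq_len(n)),
             age_bin = rep(age_bin, length.out = n),
             height_bin = rep(height_bin, length.out = n),
             weight_bin = rep(weight_bin, length.out = n),
             bmi_bin = rep(bmi_bin, length.out = n),
             mv_hours = rep(mv_hours, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("inclusion criteria keep adults ventilated at least 24 hours", {
  p <- make_patients(4)
  p$mv_hours <- c(24.0, 23.9, 500, NA)
  p$age_bin <- c("[40,65)", "[40,65)", "[0,18)", "[65,90)")
  expect_warning(kept <- apply_inclusion_criteria(p), "missing mv_hours")
  expect_identical(kept$patient_id, c("T001"))  # 24.0 inclusive boundary
  p2 <- make_patients(3); p2$mv_hours <- c(24, 25, 30)
  expect_identical(apply_inclusion_criteria(p2)$patient_id, p2$patient_id)
  empty <- apply_inclusion_criteria(make_patients(0))
  expect_equal(nrow(empty), 0)
})

test_that("k-anonymity excludes small intervals and small combination cells", {
  # an age interval with 7 patients: all 7 excluded
  p <- rbind(make_patients(7, age_bin = "[18,40)"),
             make_patients(40, age_bin = "[40,65)"))
  p$patient_id <- sprintf("T%03d", seq_len(nrow(p)))
  res <- k_anonymity_filter(p)
  expect_equal(nrow(res$retained), 40)
  expect_true(all(res$excluded$age_bin == "[18,40)"))
  expect_true(any(grepl("interval", res$report$detail[
    res$report$patient_id %in% res$excluded$patient_id])))

  # single interval per variable: one cell of 50, everyone retained
  res2 <- k_anonymity_filter(make_patients(50))
  expect_equal(nrow(res2$retained), 50)
  expect_equal(nrow(res2$report), 0)

  # two age intervals A(12), B(40): retained; shrink A to 9 -> cell 9 < 10
  p3 <- rbind(make_patients(12, age_bin = "[18,40)"),
              make_patients(40, age_bin = "[40,65)"))
  p3$patient_id <- sprintf("T%03d", seq_len(nrow(p3)))
  expect_equal(nrow(k_anonymity_filter(p3)$retained), 52)
  p4 <- p3[-(1:3), ]  # A now 9: its combination cell is re-identifiable
  res4 <- k_anonymity_filter(p4)
  expect_equal(nrow(res4$retained), 40)
  expect_true(all(res4$excluded$age_bin == "[18,40)"))
  expect_true(any(grepl("combination cell", res4$report$detail)))

  # idempotence: filtering the retained set changes nothing
  again <- k_anonymity_filter(res4$retained)
  expect_identical(again$retained, res4$retained)
})

test_that("suspected onset requires a sustained P/F drop", {
  mk <- function(times, pf) data.frame(time_h = times, pao2 = pf * 0.4,
                                       fio2 = 0.4)
  # never below threshold
  expect_true(is.na(detect_suspected_onset(mk(0:40, rep(320, 41)))))
  # drops at t = 10 and stays low for 30 h
  expect_equal(detect_suspected_onset(mk(0:40, c(rep(320, 10), rep(280, 31)))),
               10)
  # transiently low for 10 h only
  expect_true(is.na(detect_suspected_onset(
    mk(0:40, c(rep(320, 10), rep(280, 11), rep(320, 20))))))
  # a second, sustained drop is found after a transient one
  expect_equal(detect_suspected_onset(
    mk(0:60, c(rep(320, 10), rep(280, 5), rep(320, 5), rep(280, 41)))), 20)
  # charting gap over 12 h breaks sustainment
  gap <- mk(c(0, 5, 10, 11, 26, 40), c(320, 320, 280, 280, 280, 280))
  expect_true(is.na(detect_suspected_onset(gap)))
  ok_gap <- mk(c(0, 5, 10, 16, 26, 40), c(320, 320, 280, 280, 280, 280))
  expect_equal(detect_suspected_onset(ok_gap), 10)
  # record ending before 24 h of sustainment cannot confirm the onset
  expect_true(is.na(detect_suspected_onset(
    mk(0:20, c(rep(320, 5), rep(280, 16))))))
  expect_error(detect_suspected_onset(mk(5, 280)), "insufficient data")
})

test_that("window extraction is half-open around the onset", {
  obs <- data.frame(patient_id = "T001",
                    time_h = c(30, 48, 54, 71.9, 72, 80, 95.9, 96, 100),
                    variable = "pao2", value = 100)
  obs <- rbind(obs, transform(obs, variable = "fio2", value = 0.4))
  w <- pivot_observations(obs)
  ww <- extract_windows(w, t0 = 96)
  expect_equal(ww$w1$time_h, c(48, 54, 71.9))   # 72 falls into the gap
  expect_equal(ww$w2$time_h, c(96, 100))        # 96 itself is in window 2
  expect_true(ww$eligible)
  # no blood gas in window 2 -> ineligible with a reason
  w2 <- w[w$time_h < 96, ]
  ww2 <- extract_windows(w2, t0 = 96)
  expect_false(ww2$eligible)
  expect_match(ww2$reason, "window 2")
  expect_error(extract_windows(w, t0 = 40), "underflow")
})

test_that("raw features are per-window means of the ten charted variables", {
  vars <- c("pao2", "paco2", "ph", "sao2", "fio2", "peep", "vt", "rr",
            "pinsp", "hr")
  w1 <- as.data.frame(setNames(lapply(vars, function(v) c(90, 110)), vars))
  w2 <- as.data.frame(setNames(lapply(vars, function(v) 55), vars))
  rf <- raw_features(w1, w2)
  expect_true(rf$complete)
  expect_length(rf$values, 20)
  expect_equal(unname(rf$values["pao2@w1"]), 100)
  expect_equal(unname(rf$values["pao2@w2"]), 55)
  # an all-missing variable makes the patient ineligible
  w1$hr <- NA_real_
  rf2 <- raw_features(w1, w2)
  expect_false(rf2$complete)
  expect_equal(rf2$missing_vars, "hr@w1")
})

test_that("preprocessing recovers the generated onset on a synthetic cohort", {
  coh <- generate_cohort(quiet_profiles(90, 60, interval = 4), seed = 19,
                         n_comp = 20)
  prep <- preprocess_cohort(coh$patients, coh$observations)
  expect_gt(nrow(prep$eligible), 10)
  expect_equal(ncol(prep$features), 20)
  expect_false(any(is.na(prep$features)))
  el <- merge(prep$eligible, coh$ground_truth, by = "patient_id")
  ards <- el[el$archetype == "ards", ]
  expect_gte(mean(abs(ards$t0.x - ards$t0.y) <= 4), 0.9)
  # every generated patient is accounted for: eligible or reported excluded
  expect_setequal(union(prep$eligible$patient_id,
                        prep$exclusions$patient_id),
                  coh$patients$patient_id)
})
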