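test_that("archetype defaults stay inside configuration bounds", {
  arch <- archetype_defaults()
  expect_setequal(names(arch),
                  c("ards", "cardiac", "copd_like", "control"))
  for (a in arch) {
    expect_true(a$fs_anat[1] >= 0 && a$fs_anat[2] <= 0.5)
    expect_true(a$rq[1] >= 0.6 && a$rq[2] <= 1.1)
    expect_true(all(c(a$vd, a$vo2, a$sv, a$ie) > 0))
    expect_true(all(c(a$sigma_fr, a$sigma_vr) >= 0))
    expect_true(a$fcc_w1[1] >= 0 && a$fcc_w1[2] < 1)
  }
  # cardiac stroke volumes sit below control by construction
  expect_lt(mean(arch$cardiac$sv), mean(arch$control$sv))
  # the ARDS window-2 closed fraction always exceeds window 1
  expect_gt(arch$ards$fcc_w2[1], arch$ards$fcc_w1[2])
  # controls do not deteriorate
  expect_equal(arch$control$dcc, c(0, 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  prof <- quiet_profiles(6, 4)
  a <- generate_cohort(prof, seed = 5, n_comp = 20)
  b <- generate_cohort(prof, seed = 5, n_comp = 20)
  expect_identical(a$observations, b$observations)
  expect_identical(a$patients, b$patients)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_cohort(prof, seed = 6, n_comp = 20)
  expect_false(identical(a$observations, c2$observations))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "observations.csv")),
                   readLines(file.path(d2, "observations.csv")))
  back <- read_cohort(d1)
  expect_equal(nrow(back$patients), nrow(a$patients))
  expect_equal(back$manifest$seed, 5)
})

test_that("charted values equal simulator outputs under null effects", {
  coh <- generate_cohort(quiet_profiles(4, 2), seed = 9, n_comp = 20,
                         noise_sd = zero_noise, physio_cv = 0)
  wide <- pivot_observations(coh$observations)
  gt <- coh$ground_truth
  for (i in seq_len(3)) {
    g <- gt[i, ]
    w <- wide[wide$patient_id == g$patient_id, ]
    cfg <- vp_config(g$fs_anat, g$rq, g$vd, g$vo2, g$sv, g$ie, g$mu_fr,
                     g$sigma_fr, g$mu_vr, g$sigma_vr, g$ncc_w1)
    pre <- w[w$time_h < g$t0 - 6, ]
    for (r in seq_len(min(3, nrow(pre)))) {
      s <- simulate_gas_exchange(cfg,
        vent_inputs(fio2 = pre$fio2[r], vt = pre$vt[r], rr = pre$rr[r],
                    hr = pre$hr[r], hb = coh$hb), n_comp = 20)
      expect_equal(pre$pao2[r], s$pao2, tolerance = 1e-8)
      expect_equal(pre$paco2[r], s$paco2, tolerance = 1e-8)
    }
  }
})

test_that("hospital effects shift charted values by exactly the documented amounts", {
  prof_eff <- quiet_profiles(5, 3)
  prof_eff[[1]]$pao2_bias <- 5
  prof_eff[[1]]$peep_offset <- 2
  prof_eff[[1]]$fio2_rounding <- 0.05
  base <- generate_cohort(quiet_profiles(5, 3), seed = 11, n_comp = 20,
                          noise_sd = zero_noise, physio_cv = 0)
  eff <- generate_cohort(prof_eff, seed = 11, n_comp = 20,
                         noise_sd = zero_noise, physio_cv = 0)
  h1 <- base$patients$patient_id[base$patients$hospital_id == "HospX"]
  ob <- base$observations[base$observations$patient_id %in% h1, ]
  oe <- eff$observations[eff$observations$patient_id %in% h1, ]
  expect_equal(oe$value[oe$variable == "pao2"],
               ob$value[ob$variable == "pao2"] + 5)
  expect_equal(oe$value[oe$variable == "peep"],
               ob$value[ob$variable == "peep"] + 2)
  f0 <- ob$value[ob$variable == "fio2"]
  expect_equal(oe$value[oe$variable == "fio2"],
               pmin(pmax(round(f0 / 0.05) * 0.05, 0.21), 1))
  # unaffected channels identical
  expect_equal(oe$value[oe$variable == "paco2"],
               ob$value[ob$variable == "paco2"])
})

test_that("diagnosis codes are consistent with the ground truth", {
  coh <- generate_cohort(quiet_profiles(30, 20), seed = 13, n_comp = 20)
  gt <- coh$ground_truth
  codes <- strsplit(coh$patients$icd_codes, ";")
  has_j80 <- vapply(codes, function(v) "J80" %in% v, logical(1))
  expect_identical(has_j80, gt$diagnosed_ards)
  expect_true(all(gt$archetype[gt$diagnosed_ards] == "ards"))
  # under-diagnosis: not every true ARDS patient carries the code
  expect_lt(sum(gt$diagnosed_ards), sum(gt$archetype == "ards"))
  # window-2 deterioration only through closed compartments
  expect_true(all(gt$ncc_w2[gt$archetype == "ards"] >
                    gt$ncc_w1[gt$archetype == "ards"]))
  expect_true(all(gt$ncc_w2[gt$archetype == "control"] ==
                    gt$ncc_w1[gt$archetype == "control"]))
})

test_that("ARDS patients drop below the P/F threshold after onset", {
  prof <- quiet_profiles(24, 12, mix = c(ards = 1))
  coh <- generate_cohort(prof, seed = 17, n_comp = 50)
  wide <- pivot_observations(coh$observations)
  gt <- coh$ground_truth
  pf_drop <- vapply(seq_len(nrow(gt)), function(i) {
    w <- wide[wide$patient_id == gt$patient_id[i], ]
    w1 <- w[w$time_h >= gt$t0[i] - 48 & w$time_h < gt$t0[i] - 24, ]
    w2 <- w[w$time_h >= gt$t0[i] & w$time_h < gt$t0[i] + 24, ]
    mean(w2$pao2 / w2$fio2) < min(300, mean(w1$pao2 / w1$fio2))
  }, logical(1))
  expect_gte(mean(pf_drop), 0.9)
})

test_that("generator validates its configuration", {
  bad <- quiet_profiles(3, 2)
  bad[[1]]$archetype_mix <- c(ards = 0.5)
  expect_error(generate_cohort(bad, seed = 1), "sum to 1")
  bad2 <- quiet_profiles(3, 2)
  bad2[[1]]$archetype_mix <- numeric(0)
  expect_error(generate_cohort(bad2, seed = 1), "empty archetype mix")
  expect_error(generate_cohort(quiet_profiles(3, 2)[1], seed = 1))
})
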