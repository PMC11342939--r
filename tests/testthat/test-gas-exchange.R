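test_that("oxyhemoglobin dissociation curve has the expected shape", {
  expect_equal(o2_saturation(26.8), 0.499, tolerance = 0.01)
  expect_equal(o2_saturation(100), 0.977, tolerance = 0.001)
  expect_gt(o2_saturation(600), 0.999)
  # strictly increasing
  grid <- o2_saturation(seq(5, 500, by = 5))
  expect_true(all(diff(grid) > 0))
  expect_error(o2_saturation(-1), "positive")
  expect_error(o2_saturation(0), "positive")
})

test_that("O2 content combines bound and dissolved fractions", {
  expect_equal(o2_content(100, hb = 0), 0.3)
  expect_equal(o2_content(100, hb = 15), 1.34 * 15 * o2_saturation(100) + 0.3,
               tolerance = 1e-10)
  expect_lt(o2_content(60, 15), o2_content(100, 15))
  expect_lt(o2_content(100, 10), o2_content(100, 15))
  expect_error(o2_content(0, 15), "positive")
  expect_error(o2_content(100, -1), "non-negative")
})

test_that("flow distribution honours the homogeneous limit and closures", {
  cfg <- vp_config(fs_anat = 0.1, sigma_fr = 0, sigma_vr = 0, n_cc = 0)
  inp <- vent_inputs(fio2 = 0.3, vt = 500, rr = 15, hr = 80)
  fl <- distribute_flows(cfg, inp, n_comp = 10)
  expect_equal(fl$va_total, (0.5 - cfg$vd) * 15)
  expect_equal(fl$v_dot, rep(fl$va_total / 10, 10))
  expect_equal(fl$q_dot, rep(fl$q_total * 0.9 / 10, 10))
  expect_equal(sum(fl$v_dot), fl$va_total)

  # VA worked example: vt 500 mL, vd 0.15 L, rr 15 -> 5.25 L/min
  cfg2 <- vp_config(vd = 0.15)
  fl2 <- distribute_flows(cfg2, vent_inputs(fio2 = 0.21, vt = 500, rr = 15),
                          n_comp = 5)
  expect_equal(fl2$va_total, 5.25)

  # exactly n_cc closed compartments, unventilated but perfused
  cfg3 <- vp_config(sigma_fr = 0.3, sigma_vr = 0.2, n_cc = 4)
  fl3 <- distribute_flows(cfg3, inp, n_comp = 10)
  expect_equal(sum(fl3$closed), 4)
  expect_true(all(fl3$v_dot[fl3$closed] == 0))
  expect_true(all(fl3$q_dot[fl3$closed] > 0))
  expect_equal(sum(fl3$v_dot), fl3$va_total)
  expect_equal(sum(fl3$q_dot), fl3$q_total * (1 - cfg3$fs_anat))
  # closures sit on the highest flow resistances
  expect_true(min(fl3$fr[fl3$closed]) >= max(fl3$fr[!fl3$closed]))

  expect_error(distribute_flows(vp_config(vd = 0.6),
                                vent_inputs(fio2 = 0.3, vt = 500, rr = 15)),
               "zero alveolar ventilation")
  expect_error(distribute_flows(vp_config(n_cc = 10), inp, n_comp = 10),
               "closed")
})

test_that("homogeneous zero-shunt lung reproduces the alveolar gas equation", {
  vo2 <- 250; rq <- 0.8
  va <- 713 * rq * vo2 / (1000 * 40)  # alveolar ventilation giving PaCO2 ~ 40
  vt <- (va / 15 + 0.15) * 1000
  cfg <- vp_config(fs_anat = 0, rq = rq, vd = 0.15, vo2 = vo2, sv = 70,
                   sigma_fr = 0, sigma_vr = 0, n_cc = 0)
  s <- simulate_gas_exchange(cfg, vent_inputs(fio2 = 0.21, vt = vt, rr = 15,
                                              hb = 15), n_comp = 100)
  expect_true(s$converged)
  oracle <- 0.21 * 713 - s$paco2 / rq  # alveolar gas equation
  expect_lt(abs(s$pao2 - oracle), 5)
  expect_equal(s$paco2, 40, tolerance = 0.5)
  # O2 mass balance at convergence within 1%
  expect_lt(abs(s$uptake_o2 - vo2) / vo2, 0.01)
})

test_that("PaO2 falls strictly with closed compartments and rises with FiO2", {
  inp <- function(f) vent_inputs(fio2 = f, vt = 500, rr = 16, hr = 90,
                                 hb = 14)
  pao2_ncc <- sapply(seq(0, 90, 10), function(k)
    simulate_gas_exchange(vp_config(fs_anat = 0.03, vo2 = 150, sv = 100,
                                    n_cc = k), inp(1.0), n_comp = 100)$pao2)
  expect_true(all(diff(pao2_ncc) < 0))

  pao2_fio2 <- sapply(c(0.21, 0.3, 0.4, 0.6, 0.8), function(f)
    simulate_gas_exchange(vp_config(fs_anat = 0.1, n_cc = 10), inp(f),
                          n_comp = 50)$pao2)
  expect_true(all(diff(pao2_fio2) > 0))

  # PaCO2 falls as alveolar ventilation rises
  paco2_rr <- sapply(c(10, 14, 18, 22), function(r)
    simulate_gas_exchange(vp_config(),
                          vent_inputs(fio2 = 0.3, vt = 500, rr = r),
                          n_comp = 20)$paco2)
  expect_true(all(diff(paco2_rr) < 0))

  # PaO2 non-increasing in anatomical shunt
  pao2_fs <- sapply(c(0, 0.1, 0.2, 0.3), function(fs)
    simulate_gas_exchange(vp_config(fs_anat = fs), inp(0.4),
                          n_comp = 20)$pao2)
  expect_true(all(diff(pao2_fs) < 0))
})

test_that("arterial content lies between venous and best end-capillary blood", {
  cfg <- vp_config(fs_anat = 0.08, sigma_fr = 0.4, sigma_vr = 0.3, n_cc = 5)
  s <- simulate_gas_exchange(cfg, vent_inputs(fio2 = 0.4, vt = 520, rr = 15),
                             n_comp = 20)
  expect_true(s$converged)
  expect_gte(s$ca_o2, s$cv_o2)
  expect_lte(s$ca_o2, max(s$compartments$cc_o2) + 1e-9)
  expect_gte(s$shunt_fraction_total, cfg$fs_anat)
  expect_lte(s$shunt_fraction_total, 1)
})

test_that("single and 100-compartment homogeneous lungs agree", {
  cfg <- vp_config(fs_anat = 0.05, sigma_fr = 0, sigma_vr = 0, n_cc = 0)
  inp <- vent_inputs(fio2 = 0.3, vt = 480, rr = 15)
  a <- simulate_gas_exchange(cfg, inp, n_comp = 1)
  b <- simulate_gas_exchange(cfg, inp, n_comp = 100)
  expect_equal(a$pao2, b$pao2, tolerance = 1e-5)
  expect_equal(a$paco2, b$paco2, tolerance = 1e-5)
})

test_that("simulation is deterministic and handles degenerate inputs", {
  cfg <- vp_config(fs_anat = 0.1, sigma_fr = 0.5, sigma_vr = 0.2, n_cc = 7)
  inp <- vent_inputs(fio2 = 0.45, vt = 520, rr = 17, hr = 95)
  a <- simulate_gas_exchange(cfg, inp, n_comp = 30)
  b <- simulate_gas_exchange(cfg, inp, n_comp = 30)
  expect_identical(a$pao2, b$pao2)
  expect_identical(a$compartments, b$compartments)

  # fully shunted lung with zero metabolic demand: arterial = initial venous
  deg <- simulate_gas_exchange(vp_config(vo2 = 0, n_cc = 10), inp,
                               n_comp = 10)
  expect_true(deg$converged)
  expect_equal(deg$pao2, 40)
  expect_equal(deg$shunt_fraction_total, 1)
  expect_error(simulate_gas_exchange(vp_config(vo2 = 250, n_cc = 10), inp,
                                     n_comp = 10), "unsustainable VO2")

  # impossible metabolic demand raises a domain error
  expect_error(
    simulate_gas_exchange(vp_config(fs_anat = 0.5, vo2 = 3000, sv = 45,
                                    n_cc = 18),
                          vent_inputs(fio2 = 0.21, vt = 450, rr = 12,
                                      hr = 60), n_comp = 20),
    "unsustainable VO2")
})

test_that("configuration and input validation reject out-of-range values", {
  expect_error(vp_config(fs_anat = 0.6), "fs_anat")
  expect_error(vp_config(rq = 1.5), "rq")
  expect_error(vp_config(vd = -0.1), "vd")
  expect_error(vp_config(sigma_fr = -0.2), "sigma_fr")
  expect_error(vp_config(n_cc = 2.5), "integer")
  expect_error(vent_inputs(fio2 = 0.1), "fio2")
  expect_error(vent_inputs(pb = 40, ph2o = 47), "pb")
})
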