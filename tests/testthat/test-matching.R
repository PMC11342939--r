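test_that("objective is zero at truth, scaled otherwise, and order-invariant", {
  cfg <- vp_config(fs_anat = 0.05, n_cc = 2)
  w <- toy_window(config = cfg, n_comp = 20)
  expect_equal(vp_objective(cfg, w, n_comp = 20), 0, tolerance = 1e-10)

  # single timestamp, PaO2 off by +10 mmHg -> exactly 1
  w1 <- w[1, ]
  w1$pao2 <- w1$pao2 + 10
  expect_equal(vp_objective(cfg, w1, n_comp = 20), 1, tolerance = 1e-8)

  shuffled <- w[c(3, 1, 4, 2), ]
  other <- vp_config(fs_anat = 0.2, n_cc = 5)
  expect_equal(vp_objective(other, w, n_comp = 20),
               vp_objective(other, shuffled, n_comp = 20))
  expect_gt(vp_objective(other, w, n_comp = 20), 0)

  # unsustainable configurations collect the fixed penalty
  bad <- vp_config(fs_anat = 0.5, vo2 = 3000, sv = 45, n_cc = 18)
  expect_gte(vp_objective(bad, w, n_comp = 20), 1e3)
})

test_that("surrogate optimizer beats the box midpoint and is deterministic", {
  sphere <- function(x) sum((x - c(0.3, 0.7, 0.5))^2)
  a <- rbf_optimize(sphere, rep(0, 3), rep(1, 3), budget = 60, seed = 2)
  b <- rbf_optimize(sphere, rep(0, 3), rep(1, 3), budget = 60, seed = 2)
  expect_identical(a$par, b$par)
  expect_lt(a$value, sphere(rep(0.5, 3)))
  expect_lt(a$value, 1e-3)
  expect_lte(a$n_eval, 60)
  expect_error(rbf_optimize(sphere, rep(0, 3), rep(1, 3), budget = 2,
                            seed = 1), "budget")
})

test_that("window-1 fit honours the optimizer contract", {
  cfg <- vp_config(fs_anat = 0.06, rq = 0.85, vd = 0.16, vo2 = 240, sv = 75,
                   sigma_fr = 0.2, sigma_vr = 0.15, n_cc = 1)
  w <- toy_window(n_rows = 6, config = cfg, n_comp = 20)
  f1 <- fit_window1(w, budget = 60, n_comp = 20, seed = 3)
  f1b <- fit_window1(w, budget = 60, n_comp = 20, seed = 3)
  expect_identical(f1$config, f1b$config)
  # no worse than the naive midpoint start
  b <- vp_bounds(20)
  mid <- .5 * (b[, 1] + b[, 2])
  midcfg <- vp_config(mid[1], mid[2], mid[3], mid[4], mid[5], mid[6], mid[7],
                      mid[8], mid[9], mid[10], round(mid[11]))
  expect_lte(f1$objective, vp_objective(midcfg, w, n_comp = 20))
  expect_error(fit_window1(w, budget = 5), "budget")
})

test_that("window-2 scan is an argmin over the closed-compartment grid", {
  cfg <- vp_config(fs_anat = 0.06, n_cc = 1)
  cfg2 <- cfg; cfg2$n_cc <- 9L
  w2 <- toy_window(n_rows = 4, config = cfg2, n_comp = 20)
  f2 <- fit_window2(w2, cfg, n_comp = 20)
  expect_equal(f2$ncc_w2, 9L)
  expect_true(all(f2$objective <= f2$values))
  expect_gte(f2$ncc_w2, cfg$n_cc)
  # window-2 fit never touches the window-1 configuration
  expect_identical(cfg$n_cc, 1L)
})

test_that("the 2-SD acceptability criterion follows the stated rule", {
  obs <- data.frame(pao2 = c(100, 104, 96, 98), paco2 = c(40, 42, 38, 41),
                    sao2 = c(.97, .96, .975, .97), ph = c(7.4, 7.41, 7.38, 7.4))
  expect_true(assess_fit(obs, obs))
  sim <- obs
  sim$pao2 <- sim$pao2 + 2.1 * sd(obs$pao2)  # one gas beyond 2 SD
  expect_false(assess_fit(sim, obs))
  sim$pao2 <- obs$pao2 + 1.9 * sd(obs$pao2)
  expect_true(assess_fit(sim, obs))
  # constant observations (< 3 rows): fallback scales take over
  obs1 <- obs[1, ]
  sim1 <- obs1; sim1$pao2 <- sim1$pao2 + 19  # 1.9 x fallback scale of 10
  expect_true(assess_fit(sim1, obs1))
  sim1$pao2 <- obs1$pao2 + 21
  expect_false(assess_fit(sim1, obs1))
})

test_that("fitting a noise-free synthetic patient recovers its state", {
  cfg <- vp_config(fs_anat = 0.07, rq = 0.85, vd = 0.16, vo2 = 230, sv = 80,
                   sigma_fr = 0.15, sigma_vr = 0.2, n_cc = 1)
  w1 <- toy_window(n_rows = 6, config = cfg, n_comp = 20)
  cfg2 <- cfg; cfg2$n_cc <- 9L
  w2 <- toy_window(n_rows = 6, config = cfg2, n_comp = 20)
  fit <- fit_vp(w1, w2, n_comp = 20, budget = 100, seed = 5,
                patient_id = "toy")
  expect_s3_class(fit, "vp_fit")
  expect_lt(fit$obj_w1, 1)
  expect_lt(abs(fit$ncc_w2 - 9), 3)
  expect_true(fit$acceptable_w1)
  expect_gte(fit$obj_w2, 0)
  expect_output(print(fit), "window 1")
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)["ncc_w2"]), fit$ncc_w2)

  # fitted values and residuals line up with the window observations
  fv <- fitted(fit)
  expect_equal(nrow(fv), nrow(w1) + nrow(w2))
  rs <- residuals(fit)
  expect_equal(rs$pao2, c(w1$pao2, w2$pao2) - fv$pao2)
  expect_lt(max(abs(rs$pao2[rs$window == "w1"])), 15)
})

test_that("model-derived features are the documented 18 and need acceptable fits", {
  cfg <- vp_config(fs_anat = 0.05, n_cc = 1)
  w1 <- toy_window(n_rows = 4, config = cfg, n_comp = 20)
  cfg2 <- cfg; cfg2$n_cc <- 8L
  w2 <- toy_window(n_rows = 4, config = cfg2, n_comp = 20)
  # a perfectly matched virtual patient (the generating configuration)
  fit <- structure(list(patient_id = "toy", config_w1 = cfg, ncc_w2 = 8L,
                        obj_w1 = 0, obj_w2 = 0, acceptable_w1 = TRUE,
                        acceptable_w2 = TRUE, n_sim_calls = 0L, n_comp = 20,
                        w1 = w1, w2 = w2, seed = 1), class = "vp_fit")
  feats <- model_derived_features(fit)
  expect_length(feats, 18)
  expect_true(all(is.finite(feats)))
  expect_equal(unname(feats["delta_ncc"]),
               unname(feats["ncc_w2"] - feats["ncc_w1"]))
  # deterioration raises the modelled shunt fraction
  expect_gt(feats[["shunt_w2"]], feats[["shunt_w1"]])

  bad <- fit
  bad$acceptable_w2 <- FALSE
  expect_error(model_derived_features(bad), "acceptable")

  # a control patient without deterioration keeps delta_ncc near zero
  w2c <- toy_window(n_rows = 4, config = cfg, n_comp = 20)
  fitc <- fit_vp(w1, w2c, n_comp = 20, budget = 100, seed = 7)
  expect_lte(fitc$ncc_w2 - fitc$config_w1$n_cc, 2)
})
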