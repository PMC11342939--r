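#' Default optimization bounds for the eleven virtual-patient parameters
#'
#' Physiological box constraints used by the window-1 fit. The closed
#' compartment count is bounded by `min(95, n_comp - 1)` so at least one
#' compartment stays open.
#'
#' @param n_comp number of alveolar compartments of the matching model.
#' @return An 11 x 2 matrix with rownames in configuration-parameter order.
#' @export
vp_bounds <- function(n_comp = 20) {
  b <- rbind(
    fs_anat = c(0.01, 0.35), rq = c(0.7, 1.0), vd = c(0.10, 0.30),
    vo2 = c(150, 400), sv = c(40, 120), ie = c(0.25, 1.0),
    mu_fr = c(-1, 1), sigma_fr = c(0, 0.8),
    mu_vr = c(-1, 1), sigma_vr = c(0, 0.8),
    n_cc = c(0, min(95, n_comp - 1)))
  colnames(b) <- c("lower", "upper")
  b
}

.theta_to_config <- function(theta, n_comp) {
  vp_config(fs_anat = theta[1], rq = theta[2], vd = theta[3], vo2 = theta[4],
            sv = theta[5], ie = theta[6], mu_fr = theta[7],
            sigma_fr = theta[8], mu_vr = theta[9], sigma_vr = theta[10],
            n_cc = min(max(round(theta[11]), 0), n_comp - 1))
}

.gases <- c("pao2", "paco2", "sao2", "ph")

# Lean simulation path for the matching loop: returns only the charted-gas
# outputs, skipping the rich vp_sim object construction. Same physics as
# simulate_gas_exchange.
.sim_gases <- function(config, fio2, vt, rr, hr, n_comp, hb = 12, pb = 760,
                       ph2o = 47, tol = 1e-6, max_iter = 200) {
  if (vt / 1000 <= config$vd) stop("zero alveolar ventilation")
  if (config$n_cc >= n_comp) stop("all compartments closed")
  va_total <- (vt / 1000 - config$vd) * rr
  q_total <- config$sv * hr / 1000
  i <- seq_len(n_comp)
  z <- stats::qnorm((i - 0.5) / n_comp)
  fr <- exp(config$mu_fr + config$sigma_fr * z)
  vr <- exp(config$mu_vr + config$sigma_vr * z[.vr_perm(n_comp)])
  closed <- rep(FALSE, n_comp)
  if (config$n_cc > 0)
    closed[order(fr, i, decreasing = TRUE)[seq_len(config$n_cc)]] <- TRUE
  v_dot <- numeric(n_comp)
  w <- 1 / fr[!closed]
  v_dot[!closed] <- va_total * w / sum(w)
  q_dot <- q_total * (1 - config$fs_anat) * (1 / vr) / sum(1 / vr)
  res <- cpp_steady_state(v_dot, q_dot, closed, config$fs_anat, q_total,
                          fio2, pb, ph2o, hb, config$vo2, config$rq, tol,
                          max_iter, 40, 46, 1e-9)
  c(pao2 = res$pao2, paco2 = res$paco2, sao2 = res$sao2, ph = res$ph,
    converged = as.numeric(res$converged))
}

#' Simulate the model at every charted timestamp of a window
#'
#' Runs the steady-state simulator once per distinct ventilator-input row
#' (FiO2, VT, RR, HR) and maps the outputs back to the timestamps.
#'
#' @param config a [vp_config].
#' @param window wide per-window observation data frame (needs `fio2`, `vt`,
#'   `rr`, `hr`).
#' @param n_comp compartments of the matching model.
#' @param hb,pb,ph2o blood/ambient constants.
#' @return A list with `sim` (data frame of `pao2`, `paco2`, `sao2`, `ph` per
#'   timestamp) and `ok` (per-timestamp logical: simulated and converged).
#' @export
simulate_window <- function(config, window, n_comp = 20, hb = 12, pb = 760,
                            ph2o = 47) {
  stopifnot(nrow(window) >= 1)
  f <- pmin(pmax(window$fio2, 0.21), 1)
  key <- paste(round(f, 6), round(window$vt, 3), round(window$rr, 3),
               round(window$hr, 3))
  uk <- !duplicated(key)
  sims <- vector("list", sum(uk))
  names(sims) <- key[uk]
  for (i in which(uk)) {
    sims[[key[i]]] <- tryCatch(
      .sim_gases(config, fio2 = f[i], vt = window$vt[i], rr = window$rr[i],
                 hr = window$hr[i], n_comp = n_comp, hb = hb, pb = pb,
                 ph2o = ph2o),
      error = function(e) NULL)
  }
  n <- nrow(window)
  sim <- data.frame(pao2 = rep(NA_real_, n), paco2 = NA_real_,
                    sao2 = NA_real_, ph = NA_real_)
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- sims[[key[i]]]
    if (!is.null(s)) {
      sim[i, ] <- s[.gases]
      ok[i] <- s[["converged"]] > 0
    }
  }
  list(sim = sim, ok = ok)
}

#' Matching objective: scaled squared deviation of simulated from charted gases
#'
#' Mean over charted blood-gas timestamps of the sum over the four gases
#' (PaO2, PaCO2, SaO2, pH) of `((sim - obs) / scale)^2`, with the simulator
#' run at each timestamp's charted ventilator inputs. Timestamps where the
#' simulation fails or does not converge contribute the fixed `penalty`
#' instead.
#'
#' @param config a [vp_config].
#' @param window wide per-window observation data frame.
#' @param n_comp compartments of the matching model.
#' @param scales per-gas scales (mmHg, mmHg, fraction, pH units).
#' @param penalty value a failed timestamp contributes (default 1e3).
#' @param ... passed to [simulate_window()].
#' @return Non-negative scalar; zero iff the simulated gases equal the
#'   observations at every timestamp.
#' @export
vp_objective <- function(config, window, n_comp = 20,
                         scales = c(pao2 = 10, paco2 = 4, sao2 = 0.02,
                                    ph = 0.04),
                         penalty = 1e3, ...) {
  bga <- window[!is.na(window$pao2), , drop = FALSE]
  if (nrow(bga) < 1) stop("no blood-gas timestamps in window")
  sw <- simulate_window(config, bga, n_comp = n_comp, ...)
  per_t <- numeric(nrow(bga))
  for (i in seq_len(nrow(bga))) {
    if (!sw$ok[i]) { per_t[i] <- penalty; next }
    dev <- (unlist(sw$sim[i, .gases]) - unlist(bga[i, .gases])) / scales
    per_t[i] <- sum(dev^2, na.rm = TRUE)
  }
  mean(per_t)
}

#' Fit the full virtual-patient configuration in window 1
#'
#' Surrogate-based derivative-free global minimization of [vp_objective()]
#' over the 11-dimensional physiological box ([vp_bounds()]); the closed
#' compartment count is relaxed to a continuous variable during the search
#' and rounded at every evaluation. Deterministic under a fixed seed.
#'
#' @param window wide window-1 observation data frame.
#' @param budget number of objective evaluations (default 100).
#' @param n_comp compartments of the matching model (default 20).
#' @param seed integer seed for the optimizer.
#' @param bounds 11 x 2 bounds matrix.
#' @param ... passed to [vp_objective()].
#' @return A list with `config` (the best [vp_config]), `objective` and
#'   `n_sim_calls`.
#' @export
fit_window1 <- function(window, budget = 100, n_comp = 20, seed = 1,
                        bounds = vp_bounds(n_comp), ...) {
  if (budget < 11) stop("config error: budget below the problem dimension")
  fn <- function(theta)
    vp_objective(.theta_to_config(theta, n_comp), window, n_comp = n_comp,
                 ...)
  opt <- rbf_optimize(fn, bounds[, 1], bounds[, 2], budget = budget,
                      seed = seed)
  list(config = .theta_to_config(opt$par, n_comp), objective = opt$value,
       n_sim_calls = opt$n_eval)
}

#' Fit the closed-compartment count alone in window 2
#'
#' One-dimensional exhaustive scan of `n_cc` from the window-1 value to
#' `n_comp - 1`, keeping the rest of the window-1 configuration intact (the
#' window-1 parameterization is taken as the patient's steady pre-onset
#' state; only atelectasis progression is tracked). Ties go to the smallest
#' count.
#'
#' @param window wide window-2 observation data frame.
#' @param config_w1 the fitted window-1 [vp_config].
#' @param n_comp compartments of the matching model.
#' @param ... passed to [vp_objective()].
#' @return A list with `ncc_w2`, `objective` and `n_sim_calls`.
#' @export
fit_window2 <- function(window, config_w1, n_comp = 20, ...) {
  grid <- seq.int(config_w1$n_cc, n_comp - 1L)
  vals <- vapply(grid, function(k) {
    cfg <- config_w1; cfg$n_cc <- as.integer(k)
    vp_objective(cfg, window, n_comp = n_comp, ...)
  }, numeric(1))
  i <- which.min(vals)
  list(ncc_w2 = as.integer(grid[i]), objective = vals[i],
       n_sim_calls = length(grid), grid = grid, values = vals)
}

#' Fit-quality criterion: simulator outputs within 2 SD of the measurements
#'
#' For each of the four gases, the absolute difference between the mean
#' simulated and mean observed value must not exceed twice the sample SD of
#' that gas's observations in the window; with fewer than 3 observations (or
#' a degenerate zero SD) the objective scales serve as fallback SDs.
#'
#' @param sim data frame of simulated `pao2`, `paco2`, `sao2`, `ph`.
#' @param obs data frame of the corresponding observations.
#' @param scales fallback per-gas scales.
#' @return `TRUE` if the criterion holds for all four gases.
#' @export
assess_fit <- function(sim, obs,
                       scales = c(pao2 = 10, paco2 = 4, sao2 = 0.02,
                                  ph = 0.04)) {
  for (g in .gases) {
    o <- obs[[g]][!is.na(obs[[g]])]
    if (length(o) < 1) stop("no observations for gas ", g)
    s <- if (length(o) >= 3) stats::sd(o) else NA_real_
    if (!is.finite(s) || s < 1e-12) s <- scales[[g]]
    if (abs(mean(sim[[g]], na.rm = TRUE) - mean(o)) > 2 * s) return(FALSE)
  }
  TRUE
}

#' Match the virtual-patient model to one patient's two analysis windows
#'
#' The model-fitting entry point: optimizes the eleven-parameter
#' configuration against the window-1 blood gases, then tracks ARDS
#' progression by refitting the closed-compartment count alone in window 2,
#' and classifies the fit quality of both windows by the 2-SD criterion.
#'
#' @param w1,w2 wide observation data frames for the two analysis windows.
#' @param n_comp compartments of the matching model (default 20).
#' @param budget window-1 objective evaluations (default 100).
#' @param seed integer seed (deterministic fits under a fixed seed).
#' @param patient_id optional label carried into the result.
#' @param ... passed to [vp_objective()].
#' @return An object of class `vp_fit` with elements `config_w1`, `ncc_w2`,
#'   `obj_w1`, `obj_w2`, `acceptable_w1`, `acceptable_w2`, `n_sim_calls`.
#' @export
fit_vp <- function(w1, w2, n_comp = 20, budget = 100, seed = 1,
                   patient_id = NA_character_, ...) {
  f1 <- fit_window1(w1, budget = budget, n_comp = n_comp, seed = seed, ...)
  f2 <- fit_window2(w2, f1$config, n_comp = n_comp, ...)
  cfg2 <- f1$config; cfg2$n_cc <- f2$ncc_w2

  b1 <- w1[!is.na(w1$pao2), , drop = FALSE]
  b2 <- w2[!is.na(w2$pao2), , drop = FALSE]
  acc1 <- assess_fit(simulate_window(f1$config, b1, n_comp = n_comp)$sim, b1)
  acc2 <- assess_fit(simulate_window(cfg2, b2, n_comp = n_comp)$sim, b2)

  structure(list(patient_id = patient_id, config_w1 = f1$config,
                 ncc_w2 = f2$ncc_w2, obj_w1 = f1$objective,
                 obj_w2 = f2$objective, acceptable_w1 = acc1,
                 acceptable_w2 = acc2,
                 n_sim_calls = f1$n_sim_calls + f2$n_sim_calls,
                 n_comp = n_comp, w1 = w1, w2 = w2, seed = seed),
            class = "vp_fit")
}

#' @export
print.vp_fit <- function(x, ...) {
  cat(sprintf("Virtual-patient fit%s (%d-compartment model)\n",
              if (is.na(x$patient_id)) "" else paste0(" for ", x$patient_id),
              x$n_comp))
  cat(sprintf("  window 1: objective %.3f (%s), n_cc = %d\n", x$obj_w1,
              if (x$acceptable_w1) "acceptable" else "NOT acceptable",
              x$config_w1$n_cc))
  cat(sprintf("  window 2: objective %.3f (%s), n_cc = %d (delta %+d)\n",
              x$obj_w2,
              if (x$acceptable_w2) "acceptable" else "NOT acceptable",
              x$ncc_w2, x$ncc_w2 - x$config_w1$n_cc))
  invisible(x)
}

#' @export
coef.vp_fit <- function(object, ...) {
  cfg <- object$config_w1
  c(fs_anat = cfg$fs_anat, rq = cfg$rq, vd = cfg$vd, vo2 = cfg$vo2,
    sv = cfg$sv, ie = cfg$ie, mu_fr = cfg$mu_fr, sigma_fr = cfg$sigma_fr,
    mu_vr = cfg$mu_vr, sigma_vr = cfg$sigma_vr, ncc_w1 = cfg$n_cc,
    ncc_w2 = object$ncc_w2)
}

#' @export
summary.vp_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              objectives = c(w1 = object$obj_w1, w2 = object$obj_w2),
              acceptable = c(w1 = object$acceptable_w1,
                             w2 = object$acceptable_w2),
              features = tryCatch(model_derived_features(object),
                                  error = function(e) NULL))
  class(out) <- "summary.vp_fit"
  out
}

#' @export
print.summary.vp_fit <- function(x, ...) {
  cat("Virtual-patient fit summary\n\nCoefficients:\n")
  print(round(x$coef, 4))
  cat("\nObjectives: "); print(round(x$objectives, 4))
  cat("Acceptable (within 2 SD): "); print(x$acceptable)
  if (!is.null(x$features)) {
    cat("\nModel-derived features:\n"); print(round(x$features, 4))
  }
  invisible(x)
}

#' @export
fitted.vp_fit <- function(object, ...) {
  cfg2 <- object$config_w1; cfg2$n_cc <- object$ncc_w2
  b1 <- object$w1[!is.na(object$w1$pao2), , drop = FALSE]
  b2 <- object$w2[!is.na(object$w2$pao2), , drop = FALSE]
  rbind(
    cbind(window = "w1", time_h = b1$time_h,
          simulate_window(object$config_w1, b1, n_comp = object$n_comp)$sim),
    cbind(window = "w2", time_h = b2$time_h,
          simulate_window(cfg2, b2, n_comp = object$n_comp)$sim))
}

#' @export
residuals.vp_fit <- function(object, ...) {
  f <- fitted(object)
  b1 <- object$w1[!is.na(object$w1$pao2), , drop = FALSE]
  b2 <- object$w2[!is.na(object$w2$pao2), , drop = FALSE]
  obs <- rbind(b1[, .gases], b2[, .gases])
  res <- obs - f[, .gases]
  cbind(f[, c("window", "time_h")], res)
}

#' The 18 model-derived features of a fitted virtual patient
#'
#' The identified window-1 configuration parameters (anatomical shunt,
#' respiratory quotient, dead space, O2 consumption, stroke volume, the
#' resistance-dispersion scales and the closed-compartment count); the
#' window-2 closed-compartment count and its increase over window 1; and
#' simulator outputs at the window-mean ventilator inputs: total alveolar
#' ventilation, total shunt fraction and arterial O2 content in both windows,
#' plus mixed-venous O2 saturation in both windows. The three configuration
#' entries that the steady-state model leaves structurally unidentified (the
#' I:E ratio, which is metadata, and the two resistance location parameters,
#' which cancel out of the flow distributions) are fitted but excluded here:
#' their optimized values carry no information about the patient and would
#' only inject optimizer noise into the feature space.
#' Requires acceptable fits in both windows: patients failing either window
#' carry no reliable model-derived data.
#'
#' @param fit a [fit_vp()] result.
#' @param hb,pb,ph2o blood/ambient constants for the summary simulations.
#' @return A named numeric vector of length 18.
#' @export
model_derived_features <- function(fit, hb = 12, pb = 760, ph2o = 47) {
  stopifnot(inherits(fit, "vp_fit"))
  if (!(fit$acceptable_w1 && fit$acceptable_w2))
    stop("model-derived features require acceptable fits in both windows")
  cfg1 <- fit$config_w1
  cfg2 <- cfg1; cfg2$n_cc <- fit$ncc_w2
  mean_inputs <- function(w)
    vent_inputs(fio2 = min(max(mean(w$fio2, na.rm = TRUE), 0.21), 1),
                vt = mean(w$vt, na.rm = TRUE), rr = mean(w$rr, na.rm = TRUE),
                hr = mean(w$hr, na.rm = TRUE), hb = hb, pb = pb, ph2o = ph2o)
  s1 <- simulate_gas_exchange(cfg1, mean_inputs(fit$w1), n_comp = fit$n_comp)
  s2 <- simulate_gas_exchange(cfg2, mean_inputs(fit$w2), n_comp = fit$n_comp)
  out <- c(fs_anat = cfg1$fs_anat, rq = cfg1$rq, vd = cfg1$vd,
           vo2 = cfg1$vo2, sv = cfg1$sv,
           sigma_fr = cfg1$sigma_fr, sigma_vr = cfg1$sigma_vr,
           ncc_w1 = cfg1$n_cc,
           ncc_w2 = fit$ncc_w2, delta_ncc = fit$ncc_w2 - cfg1$n_cc,
           va_w1 = s1$va_total, va_w2 = s2$va_total,
           shunt_w1 = s1$shunt_fraction_total,
           shunt_w2 = s2$shunt_fraction_total,
           cao2_w1 = s1$ca_o2, cao2_w2 = s2$ca_o2,
           svo2_w1 = s1$svo2, svo2_w2 = s2$svo2)
  stopifnot(length(out) == 18, all(is.finite(out)))
  out
}
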