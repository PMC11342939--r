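#' Virtual-patient configuration
#'
#' Bundles the eleven individualized parameters of the multi-compartment
#' gas-exchange model: the six rarely measured physiological parameters
#' (anatomical shunt fraction, respiratory quotient, anatomical dead space,
#' metabolic O2 consumption, cardiac stroke volume, inspiration-to-expiration
#' ratio), the log-normal location/scale of the per-compartment flow and
#' vascular resistances, and the number of closed alveolar compartments
#' `n_cc`, which represents atelectasis (perfused but unventilated lung
#' units, i.e. complete alveolar shunt).
#'
#' @param fs_anat anatomical shunt fraction, in `[0, 0.5]`.
#' @param rq respiratory quotient (CO2 production / O2 consumption), in
#'   `[0.6, 1.1]`.
#' @param vd anatomical dead space volume (L), positive.
#' @param vo2 metabolic O2 consumption (mL/min STPD), non-negative.
#' @param sv cardiac stroke volume (mL), positive.
#' @param ie inspiration-to-expiration ratio. Carried (and fitted) as part of
#'   the configuration but not used by the steady-state gas-exchange core,
#'   which has no intra-breath dynamics.
#' @param mu_fr,sigma_fr log-normal location and scale of the per-compartment
#'   flow resistances (arbitrary units; only relative resistances matter).
#' @param mu_vr,sigma_vr log-normal location and scale of the per-compartment
#'   vascular resistances.
#' @param n_cc integer number of closed alveolar compartments.
#'
#' @return An object of class `vp_config`.
#' @export
vp_config <- function(fs_anat = 0.03, rq = 0.85, vd = 0.15, vo2 = 250,
                      sv = 70, ie = 0.5, mu_fr = 0, sigma_fr = 0.2,
                      mu_vr = 0, sigma_vr = 0.2, n_cc = 0L) {
  stopifnot(
    "fs_anat must be in [0, 0.5]" = fs_anat >= 0 && fs_anat <= 0.5,
    "rq must be in [0.6, 1.1]" = rq >= 0.6 && rq <= 1.1,
    "vd must be positive" = vd > 0,
    "vo2 must be non-negative" = vo2 >= 0,
    "sv must be positive" = sv > 0,
    "ie must be positive" = ie > 0,
    "sigma_fr must be non-negative" = sigma_fr >= 0,
    "sigma_vr must be non-negative" = sigma_vr >= 0,
    "n_cc must be a non-negative integer" =
      n_cc >= 0 && abs(n_cc - round(n_cc)) < 1e-8
  )
  structure(list(fs_anat = fs_anat, rq = rq, vd = vd, vo2 = vo2, sv = sv,
                 ie = ie, mu_fr = mu_fr, sigma_fr = sigma_fr, mu_vr = mu_vr,
                 sigma_vr = sigma_vr, n_cc = as.integer(round(n_cc))),
            class = "vp_config")
}

#' @export
print.vp_config <- function(x, ...) {
  cat("Virtual-patient configuration\n")
  cat(sprintf("  anatomical shunt fs_anat = %.3f, n_cc = %d closed compartments\n",
              x$fs_anat, x$n_cc))
  cat(sprintf("  rq = %.2f, vd = %.3f L, vo2 = %.0f mL/min, sv = %.0f mL, ie = %.2f\n",
              x$rq, x$vd, x$vo2, x$sv, x$ie))
  cat(sprintf("  flow resistance lognormal(%.2f, %.2f); vascular lognormal(%.2f, %.2f)\n",
              x$mu_fr, x$sigma_fr, x$mu_vr, x$sigma_vr))
  invisible(x)
}

#' Ventilator and physiological inputs for one simulation
#'
#' The routinely charted quantities the simulator consumes. PEEP and
#' temperature are carried as metadata only (the mechanical sub-model is out
#' of scope); they still feed the raw-feature clustering arm.
#'
#' @param fio2 inspired O2 fraction, in `[0.21, 1]`.
#' @param vt tidal volume (mL).
#' @param rr respiratory rate (breaths/min).
#' @param peep positive end-expiratory pressure (cmH2O, metadata).
#' @param hr heart rate (beats/min).
#' @param hb hemoglobin (g/dL); default 12 g/dL.
#' @param pb barometric pressure (mmHg).
#' @param ph2o water vapor pressure (mmHg); must be below `pb`.
#' @param temp body temperature (deg C, metadata).
#'
#' @return An object of class `vent_inputs`.
#' @export
vent_inputs <- function(fio2 = 0.21, vt = 500, rr = 14, peep = 5, hr = 80,
                        hb = 12, pb = 760, ph2o = 47, temp = 37) {
  stopifnot(
    "fio2 must be in [0.21, 1]" = fio2 >= 0.21 && fio2 <= 1,
    "vt must be positive" = vt > 0,
    "rr must be positive" = rr > 0,
    "hr must be positive" = hr > 0,
    "hb must be non-negative" = hb >= 0,
    "pb must exceed ph2o" = pb > ph2o
  )
  structure(list(fio2 = fio2, vt = vt, rr = rr, peep = peep, hr = hr,
                 hb = hb, pb = pb, ph2o = ph2o, temp = temp),
            class = "vent_inputs")
}

#' Oxyhemoglobin saturation (Severinghaus form)
#'
#' `S(p) = 1 / (1 + 23400 / (p^3 + 150 p))`; strictly increasing with
#' asymptote 1.
#'
#' @param po2 O2 partial pressure (mmHg), positive.
#' @return Saturation as a fraction in (0, 1).
#' @export
o2_saturation <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 <= 0))
    stop("po2 must be positive")
  cpp_o2_saturation(as.numeric(po2))
}

#' Arterial O2 content
#'
#' Hemoglobin-bound plus dissolved O2: `1.34 * hb * S(po2) + 0.003 * po2`
#' (mL O2 / dL blood).
#'
#' @param po2 O2 partial pressure (mmHg), positive.
#' @param hb hemoglobin (g/dL), non-negative (zero gives the dissolved-only
#'   limit).
#' @return O2 content in mL/dL.
#' @export
o2_content <- function(po2, hb) {
  if (any(!is.finite(po2)) || any(po2 <= 0))
    stop("po2 must be positive")
  if (!is.finite(hb) || hb < 0)
    stop("hb must be non-negative")
  cpp_o2_content(as.numeric(po2), hb)
}

#' Blood CO2 content (linear approximation)
#'
#' `0.45 * pco2 + 26.7` mL CO2 / dL blood, a linearization of the CO2
#' dissociation relation around the physiological range.
#'
#' @param pco2 CO2 partial pressure (mmHg), positive.
#' @return CO2 content in mL/dL.
#' @export
co2_content <- function(pco2) {
  if (any(!is.finite(pco2)) || any(pco2 <= 0))
    stop("pco2 must be positive")
  0.45 * pco2 + 26.7
}

# rank of the golden-ratio (Weyl) sequence: a fixed, well-spread permutation
.vr_perm <- function(n) rank((seq_len(n) * (sqrt(5) - 1) / 2) %% 1,
                             ties.method = "first")

#' Distribute ventilation and perfusion over alveolar compartments
#'
#' Per-compartment flow and vascular resistances are deterministic log-normal
#' quantiles `exp(mu + sigma * qnorm((i - 0.5) / n_comp))`, not random draws,
#' so the distribution parameters (not the draws) are the individualized
#' quantities; the vascular-resistance quantiles are assigned through a fixed
#' low-discrepancy permutation of the compartment index, decorrelating the
#' two resistances. The `n_cc` compartments of highest flow resistance are closed
#' (atelectatic): they receive no ventilation but keep their perfusion,
#' i.e. complete alveolar shunt. Total alveolar ventilation
#' `VA = (vt/1000 - vd) * rr` is split over open compartments proportionally
#' to inverse flow resistance; non-shunted perfusion `Q * (1 - fs_anat)` with
#' `Q = sv * hr / 1000` is split over all compartments proportionally to
#' inverse vascular resistance.
#'
#' @param config a [vp_config].
#' @param inputs a [vent_inputs].
#' @param n_comp number of alveolar compartments (default 100).
#' @return A list with per-compartment `v_dot`, `q_dot` (L/min), resistances
#'   `fr`, `vr`, logical `closed`, and totals `va_total`, `q_total`.
#' @export
distribute_flows <- function(config, inputs, n_comp = 100) {
  stopifnot(inherits(config, "vp_config"), inherits(inputs, "vent_inputs"),
            n_comp >= 1)
  if (config$n_cc >= n_comp)
    stop("all compartments closed: n_cc must be below n_comp")
  if (inputs$vt / 1000 <= config$vd)
    stop("zero alveolar ventilation: tidal volume does not exceed dead space")
  va_total <- (inputs$vt / 1000 - config$vd) * inputs$rr
  q_total <- config$sv * inputs$hr / 1000

  i <- seq_len(n_comp)
  z <- stats::qnorm((i - 0.5) / n_comp)
  fr <- exp(config$mu_fr + config$sigma_fr * z)
  # vascular-resistance quantiles are assigned by a deterministic
  # low-discrepancy (golden-ratio) permutation of the compartment index, so
  # flow and vascular resistance are decorrelated across compartments and
  # closed compartments carry a perfusion share that does not degenerate
  # with sigma_vr
  vr <- exp(config$mu_vr + config$sigma_vr * z[.vr_perm(n_comp)])

  closed <- rep(FALSE, n_comp)
  if (config$n_cc > 0) {
    # highest flow resistance first; ties broken towards the last index
    ord <- order(fr, i, decreasing = TRUE)
    closed[ord[seq_len(config$n_cc)]] <- TRUE
  }

  v_dot <- numeric(n_comp)
  w <- 1 / fr[!closed]
  v_dot[!closed] <- va_total * w / sum(w)
  wq <- 1 / vr
  q_dot <- q_total * (1 - config$fs_anat) * wq / sum(wq)

  list(v_dot = v_dot, q_dot = q_dot, fr = fr, vr = vr, closed = closed,
       va_total = va_total, q_total = q_total)
}

#' Steady-state multi-compartment gas-exchange simulation
#'
#' Solves the coupled alveolar/blood-side O2 and CO2 mass balances by
#' fixed-point iteration over the mixed-venous contents: per open compartment
#' a monotone 1-D root find yields the alveolar partial pressures given the
#' current venous contents; end-capillary blood is mixed flow-weighted with
#' the shunted venous blood (anatomical shunt plus closed compartments) to
#' give arterial contents; the Fick principle updates the venous contents
#' (`CvO2 = CaO2 - vo2/(10 Q)`, `CvCO2 = CaCO2 + rq * vo2/(10 Q)`).
#'
#' @param config a [vp_config].
#' @param inputs a [vent_inputs].
#' @param n_comp number of alveolar compartments (default 100).
#' @param tol relative convergence tolerance on the venous contents.
#' @param max_iter maximum number of fixed-point iterations; non-convergence
#'   returns a result with `converged = FALSE` rather than an error.
#' @param pv_o2_init,pv_co2_init initial mixed-venous partial pressures
#'   (mmHg) seeding the iteration.
#'
#' @return An object of class `vp_sim` with arterial `pao2`, `paco2`, `sao2`
#'   (fraction), `ph`, mixed-venous saturation `svo2`, totals `va_total`,
#'   `q_total`, `shunt_fraction_total`, a per-compartment data frame
#'   `compartments`, and convergence information. `converged` is `TRUE` only
#'   if the venous fixed point met `tol` and the gas-side O2 uptake matches
#'   `vo2` within 1%.
#' @export
simulate_gas_exchange <- function(config, inputs, n_comp = 100, tol = 1e-6,
                                  max_iter = 200, pv_o2_init = 40,
                                  pv_co2_init = 46) {
  stopifnot(inherits(config, "vp_config"), inherits(inputs, "vent_inputs"))

  if (config$n_cc >= n_comp) {
    # fully shunted lung: no gas exchange is possible; only a zero metabolic
    # demand admits a steady state, in which arterial = venous = initial
    if (config$vo2 > 0)
      stop("unsustainable VO2: all compartments closed with positive VO2")
    comp <- data.frame(v_dot = rep(0, n_comp),
                       q_dot = rep(config$sv * inputs$hr / 1000 *
                                     (1 - config$fs_anat) / n_comp, n_comp),
                       pa_o2 = NA_real_, pa_co2 = NA_real_,
                       cc_o2 = o2_content(pv_o2_init, inputs$hb),
                       cc_co2 = co2_content(pv_co2_init),
                       closed = TRUE)
    out <- list(pao2 = pv_o2_init, paco2 = pv_co2_init,
                sao2 = o2_saturation(pv_o2_init),
                ph = 6.1 + log10(24 / (0.03 * pv_co2_init)),
                svo2 = o2_saturation(pv_o2_init),
                va_total = 0, q_total = config$sv * inputs$hr / 1000,
                shunt_fraction_total = 1, compartments = comp,
                converged = TRUE, n_iter = 0L,
                uptake_o2 = 0, config = config, inputs = inputs,
                n_comp = n_comp)
    class(out) <- "vp_sim"
    return(out)
  }

  fl <- distribute_flows(config, inputs, n_comp)
  res <- cpp_steady_state(fl$v_dot, fl$q_dot, fl$closed, config$fs_anat,
                          fl$q_total, inputs$fio2, inputs$pb, inputs$ph2o,
                          inputs$hb, config$vo2, config$rq, tol, max_iter,
                          pv_o2_init, pv_co2_init, 1e-9)
  comp <- data.frame(v_dot = fl$v_dot, q_dot = fl$q_dot,
                     pa_o2 = res$pa_o2, pa_co2 = res$pa_co2,
                     cc_o2 = res$cc_o2, cc_co2 = res$cc_co2,
                     closed = fl$closed)
  out <- list(pao2 = res$pao2, paco2 = res$paco2, sao2 = res$sao2,
              ph = res$ph, svo2 = res$svo2, va_total = fl$va_total,
              q_total = fl$q_total,
              shunt_fraction_total = res$shunt_fraction_total,
              compartments = comp, converged = res$converged,
              n_iter = res$n_iter, uptake_o2 = res$uptake_o2,
              ca_o2 = res$ca_o2, cv_o2 = res$cv_o2, ca_co2 = res$ca_co2,
              cv_co2 = res$cv_co2,
              config = config, inputs = inputs, n_comp = n_comp)
  class(out) <- "vp_sim"
  out
}

#' @export
print.vp_sim <- function(x, ...) {
  cat(sprintf("Steady-state gas exchange (%d compartments, %s)\n",
              x$n_comp,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  cat(sprintf("  PaO2 %.1f mmHg  PaCO2 %.1f mmHg  SaO2 %.3f  pH %.2f  SvO2 %.3f\n",
              x$pao2, x$paco2, x$sao2, x$ph, x$svo2))
  cat(sprintf("  VA %.2f L/min  Q %.2f L/min  total shunt fraction %.3f\n",
              x$va_total, x$q_total, x$shunt_fraction_total))
  invisible(x)
}
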