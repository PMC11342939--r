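#' Default disease-archetype library for the synthetic cohort
#'
#' Each archetype specifies uniform sampling ranges for the eleven
#' virtual-patient parameters, the window-1 closed-compartment fraction
#' `fcc_w1`, the window-2 closed-compartment state (`fcc_w2`, absolute range
#' for the ARDS archetype; a positive increment `dcc` for the
#' cardiac-failure-like and COPD-like archetypes, whose oxygenation also
#' deteriorates around onset, which is what brings them into a suspected-ARDS
#' cohort in the first place), a heart-rate range and the ICD-10 codes the
#' archetype carries. Controls do not deteriorate and are therefore mostly
#' removed by the onset-detection rule, emulating patients who never meet the
#' oxygenation-based suspicion criterion.
#'
#' @return A named list of archetype specifications
#'   (`ards`, `cardiac`, `copd_like`, `control`).
#' @export
archetype_defaults <- function() {
  base <- list(
    fs_anat = c(0.02, 0.06), rq = c(0.78, 0.92), vd = c(0.13, 0.19),
    vo2 = c(220, 300), sv = c(60, 90), ie = c(0.45, 0.70),
    mu_fr = c(-0.2, 0.2), sigma_fr = c(0.05, 0.30),
    mu_vr = c(-0.2, 0.2), sigma_vr = c(0.05, 0.30),
    fcc_w1 = c(0, 0.05), dcc = c(0, 0), fcc_w2 = NULL,
    hr = c(70, 105), icd = character()
  )
  ards <- utils::modifyList(base, list(
    fs_anat = c(0.03, 0.09), fcc_w1 = c(0, 0.10),
    fcc_w2 = c(0.30, 0.60), dcc = NULL,
    vo2 = c(180, 250), sv = c(70, 95),
    icd = "J96"  # acute respiratory failure; J80 added only when diagnosed
  ))
  cardiac <- utils::modifyList(base, list(
    sv = c(35, 55), fs_anat = c(0.03, 0.08), hr = c(95, 125),
    vo2 = c(200, 280), dcc = c(0.10, 0.20), icd = "I50"
  ))
  copd <- utils::modifyList(base, list(
    vd = c(0.22, 0.30), sigma_fr = c(0.30, 0.60),
    dcc = c(0.10, 0.20), icd = "J44"
  ))
  control <- utils::modifyList(base, list(icd = "Z99"))
  list(ards = ards, cardiac = cardiac, copd_like = copd, control = control)
}

#' Default multi-hospital profiles
#'
#' Three hospitals with distinct systematic effects: arterial blood-gas
#' analyzer offsets on PaO2, PEEP charting offsets, FiO2 charting grids,
#' charting frequency and tidal-volume-per-kg ventilation policies, plus
#' different archetype case mixes. The magnitudes are package defaults chosen
#' to make hospital-driven clustering bias reproducible at a cohort of around
#' 200 patients; all are configurable.
#'
#' @param n_patients integer vector of cohort sizes per hospital.
#' @return A list of hospital profile lists.
#' @export
hospital_profiles_default <- function(n_patients = c(80, 60, 60)) {
  stopifnot(length(n_patients) == 3)
  list(
    list(hospital_id = "HospA", n_patients = n_patients[1],
         pao2_bias = 5, peep_offset = 0, fio2_rounding = 0.05,
         charting_interval = 2, vt_per_kg = 6,
         archetype_mix = c(ards = 0.30, cardiac = 0.25, copd_like = 0.25,
                           control = 0.20)),
    list(hospital_id = "HospB", n_patients = n_patients[2],
         pao2_bias = -5, peep_offset = 2, fio2_rounding = 0.05,
         charting_interval = 4, vt_per_kg = 8,
         archetype_mix = c(ards = 0.35, cardiac = 0.20, copd_like = 0.25,
                           control = 0.20)),
    list(hospital_id = "HospC", n_patients = n_patients[3],
         pao2_bias = 0, peep_offset = 0, fio2_rounding = 0.10,
         charting_interval = 8, vt_per_kg = 7,
         archetype_mix = c(ards = 0.25, cardiac = 0.30, copd_like = 0.25,
                           control = 0.20))
  )
}

#' Default measurement-noise standard deviations
#'
#' Additive Gaussian noise applied to charted blood-gas values, reflecting
#' typical analyzer repeatability. SaO2 is carried as a fraction.
#' @return Named numeric vector of SDs.
#' @export
noise_defaults <- function() {
  c(pao2 = 5, paco2 = 2, ph = 0.02, sao2 = 0.01, pinsp = 1)
}

.draw <- function(range) stats::runif(1, range[1], range[2])

#' Generate a synthetic multi-hospital ICU cohort with known ground truth
#'
#' For every patient an archetype is drawn from the hospital's case mix and a
#' true virtual-patient configuration from the archetype's parameter ranges.
#' Blood gases are then simulated with the mechanistic gas-exchange model at
#' the hospital's charting interval over `[t0 - 60h, t0 + 36h]`, where `t0`
#' (suspected-onset time, drawn uniformly on 48-120 h after admission and
#' snapped to the charting grid) is the time the closed-compartment count
#' reaches its window-2 value; the transition is a linear ramp over the 6 h
#' before `t0`, so the transient stays inside the excluded gap between the
#' analysis windows. Hospital effects (PaO2 analyzer bias, PEEP offset, FiO2
#' charting grid) are applied to the charted values, followed by i.i.d.
#' Gaussian measurement noise. Only a fraction `p_dx` of true-ARDS patients
#' carries the J80 diagnosis code (under-diagnosis).
#'
#' @param hospital_profiles list of hospital profiles, see
#'   [hospital_profiles_default()].
#' @param archetypes archetype library, see [archetype_defaults()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param n_comp number of alveolar compartments of the generating model.
#' @param noise_sd named vector of measurement-noise SDs (`pao2`, `paco2`,
#'   `ph`, `sao2`, `pinsp`); zero everywhere gives noise-free charts.
#' @param p_dx probability that a true-ARDS patient carries the J80 code.
#' @param hb hemoglobin (g/dL) used in the generating simulations.
#' @param physio_cv log-normal coefficient of variation of the slow
#'   within-patient physiological fluctuation of stroke volume and O2
#'   consumption between charting rows; `0` freezes the physiology.
#'
#' @return A list of class `vp_cohort` with data frames `patients`,
#'   `observations` (long format: `patient_id`, `time_h`, `variable`,
#'   `value`) and `ground_truth`.
#' @export
generate_cohort <- function(hospital_profiles = hospital_profiles_default(),
                            archetypes = archetype_defaults(), seed = 1,
                            n_comp = 100, noise_sd = noise_defaults(),
                            p_dx = 0.6, hb = 12, physio_cv = 0.10) {
  stopifnot(length(hospital_profiles) >= 2)
  hospital_profiles <- lapply(hospital_profiles, function(hp) {
    hp$archetype_mix <- unlist(hp$archetype_mix)  # YAML delivers named lists
    if (length(hp$archetype_mix) && is.null(names(hp$archetype_mix)))
      stop("config error: archetype_mix must be a named mapping")
    hp
  })
  for (hp in hospital_profiles) {
    if (length(hp$archetype_mix) == 0)
      stop("config error: empty archetype mix for ", hp$hospital_id)
    if (abs(sum(hp$archetype_mix) - 1) > 1e-9)
      stop("config error: archetype mix must sum to 1 for ", hp$hospital_id)
    if (hp$charting_interval <= 0)
      stop("config error: charting interval must be positive")
  }
  ns <- function(v) if (is.na(noise_sd[v]) || noise_sd[v] == 0) 0 else
    stats::rnorm(1, 0, noise_sd[v])

  with_seed(seed, {
    pat_rows <- list(); obs_rows <- list(); gt_rows <- list()
    pid_n <- 0L
    for (hp in hospital_profiles) {
      for (j in seq_len(hp$n_patients)) {
        pid_n <- pid_n + 1L
        pid <- sprintf("P%04d", pid_n)
        arch_name <- sample(names(hp$archetype_mix), 1,
                            prob = hp$archetype_mix)
        a <- archetypes[[arch_name]]

        # biometrics: coarse k-anonymity bins
        age <- stats::runif(1, 20, 88)
        age_bin <- c("[18,40)", "[40,65)", "[65,90)")[
          findInterval(age, c(18, 40, 65))]
        w_idx <- sample(1:2, 1)
        weight_bin <- c("[50,80)", "[80,110)")[w_idx]
        weight <- stats::runif(1, c(55, 80)[w_idx], c(80, 105)[w_idx])
        height_bin <- "[155,190)"
        bmi_bin <- "[18,35)"
        mv_hours <- if (stats::runif(1) < 0.05) stats::runif(1, 6, 23)
                    else stats::runif(1, 48, 600)

        # true VP configuration (window 1)
        ncc_w1 <- as.integer(round(.draw(a$fcc_w1) * n_comp))
        ncc_w2 <- if (!is.null(a$fcc_w2))
          as.integer(round(.draw(a$fcc_w2) * n_comp))
        else
          ncc_w1 + as.integer(round(.draw(a$dcc) * n_comp))
        ncc_w2 <- min(ncc_w2, n_comp - 1L)
        cfg <- vp_config(fs_anat = .draw(a$fs_anat), rq = .draw(a$rq),
                         vd = .draw(a$vd), vo2 = .draw(a$vo2),
                         sv = .draw(a$sv), ie = .draw(a$ie),
                         mu_fr = .draw(a$mu_fr), sigma_fr = .draw(a$sigma_fr),
                         mu_vr = .draw(a$mu_vr), sigma_vr = .draw(a$sigma_vr),
                         n_cc = ncc_w1)
        deteriorates <- ncc_w2 > ncc_w1

        intv <- hp$charting_interval
        t0 <- round(stats::runif(1, 48, 120) / intv) * intv
        t0 <- min(max(t0, 48), 120)

        diagnosed <- (arch_name == "ards") && (stats::runif(1) < p_dx)
        icd <- a$icd
        if (diagnosed) icd <- c("J80", icd)

        # ventilation course
        fio2_base <- sample(c(0.30, 0.35, 0.40), 1)
        # per-kg ventilation policy with physician adherence scatter
        vt <- round((hp$vt_per_kg + stats::rnorm(1, 0, 0.4)) * weight)
        rr_base <- sample(14:22, 1)
        peep_base <- sample(5:8, 1)
        hr_base <- stats::runif(1, a$hr[1], a$hr[2])
        crs_w1 <- stats::runif(1, 40, 60)
        crs_w2 <- if (arch_name == "ards") stats::runif(1, 20, 35)
                  else stats::runif(1, 35, 55)

        t_start <- ceiling(max(0, t0 - 60) / intv) * intv
        times <- seq(t_start, t0 + 36, by = intv)
        for (t in times) {
          ncc_t <- if (t < t0 - 6) ncc_w1
            else if (t < t0)
              as.integer(round(ncc_w1 + (ncc_w2 - ncc_w1) * (t - (t0 - 6)) / 6))
            else ncc_w2
          # row-level FiO2/VT/RR titration (charted care variation) plus the
          # post-onset escalation for deteriorating patients; support is never
          # titrated down once a deteriorating patient approaches onset
          post <- t >= t0 - 6 && deteriorates
          fio2_t <- fio2_base + (if (post) sample(c(0, 0.05), 1) else
                                   sample(c(-0.05, 0, 0, 0.05), 1)) +
            (if (t >= t0 && deteriorates) 0.15 else 0)
          fio2_t <- min(max(fio2_t, 0.25), 1)
          rr_t <- max(8, rr_base + sample(c(-4, -2, 0, 2, 4), 1))
          vt_t <- round(vt * (if (post) sample(c(1, 1.15), 1) else
                                sample(c(0.85, 1, 1.15), 1)))
          # care teams never ventilate at or below the dead space volume
          vt_t <- max(vt_t, round(cfg$vd * 1000 + 150))
          hr_t <- round(hr_base + ns_num(noise_sd, 3))
          peep_t <- peep_base + (if (t >= t0 && deteriorates) 3 else 0) +
            hp$peep_offset
          crs_t <- if (t < t0) crs_w1 else crs_w2

          cfg_t <- cfg; cfg_t$n_cc <- ncc_t
          # slow physiological fluctuation of the hemodynamic/metabolic state
          # between charting rows (charted gases are snapshots of a moving
          # target, not repeated measurements of a constant)
          if (physio_cv > 0) {
            cfg_t$sv <- cfg$sv * exp(stats::rnorm(1, 0, physio_cv))
            cfg_t$vo2 <- cfg$vo2 * exp(stats::rnorm(1, 0, physio_cv))
          }
          sim <- .sim_gases(cfg_t, fio2 = fio2_t, vt = vt_t, rr = rr_t,
                            hr = hr_t, n_comp = n_comp, hb = hb)

          vals <- c(
            pao2 = sim[["pao2"]] + hp$pao2_bias + ns("pao2"),
            paco2 = sim[["paco2"]] + ns("paco2"),
            ph = sim[["ph"]] + ns("ph"),
            sao2 = min(max(sim[["sao2"]] + ns("sao2"), 0.3), 1),
            fio2 = if (hp$fio2_rounding > 0)
              min(max(round(fio2_t / hp$fio2_rounding) * hp$fio2_rounding,
                      0.21), 1) else fio2_t,
            peep = peep_t, vt = vt_t, rr = rr_t,
            pinsp = peep_t + vt / crs_t + ns("pinsp"),
            hr = hr_t
          )
          obs_rows[[length(obs_rows) + 1L]] <-
            data.frame(patient_id = pid, time_h = t,
                       variable = names(vals), value = unname(vals))
        }

        pat_rows[[length(pat_rows) + 1L]] <- data.frame(
          patient_id = pid, hospital_id = hp$hospital_id,
          age_bin = age_bin, height_bin = height_bin,
          weight_bin = weight_bin, bmi_bin = bmi_bin,
          icd_codes = paste(icd, collapse = ";"), mv_hours = mv_hours)
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          patient_id = pid, hospital_id = hp$hospital_id,
          archetype = arch_name, diagnosed_ards = diagnosed, t0 = t0,
          n_comp = n_comp, fs_anat = cfg$fs_anat, rq = cfg$rq, vd = cfg$vd,
          vo2 = cfg$vo2, sv = cfg$sv, ie = cfg$ie, mu_fr = cfg$mu_fr,
          sigma_fr = cfg$sigma_fr, mu_vr = cfg$mu_vr,
          sigma_vr = cfg$sigma_vr, ncc_w1 = ncc_w1, ncc_w2 = ncc_w2,
          fio2_base = fio2_base, vt = vt, rr_base = rr_base,
          hr_base = hr_base)
      }
    }
    out <- list(patients = do.call(rbind, pat_rows),
                observations = do.call(rbind, obs_rows),
                ground_truth = do.call(rbind, gt_rows),
                seed = seed, n_comp = n_comp, noise_sd = noise_sd,
                p_dx = p_dx, hb = hb, physio_cv = physio_cv,
                hospital_profiles = hospital_profiles)
    rownames(out$observations) <- NULL
    class(out) <- "vp_cohort"
    out
  })
}

# jitter helper: zero when all noise is switched off so that the
# noise-free cohort is fully deterministic given the parameter draws
ns_num <- function(noise_sd, sd) {
  if (all(noise_sd == 0)) 0 else stats::rnorm(1, 0, sd)
}

#' @export
print.vp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d patients, %d hospitals, %d charted rows\n",
              nrow(x$patients), length(unique(x$patients$hospital_id)),
              nrow(x$observations)))
  print(table(x$ground_truth$archetype))
  invisible(x)
}

#' Write a synthetic cohort to CSV files plus a YAML manifest
#'
#' @param cohort a `vp_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cohort$seed, n_comp = cohort$n_comp,
                   p_dx = cohort$p_dx, hb = cohort$hb,
                   physio_cv = cohort$physio_cv,
                   noise_sd = as.list(cohort$noise_sd),
                   hospitals = lapply(cohort$hospital_profiles, function(h) {
                     h$archetype_mix <- as.list(h$archetype_mix); h
                   }))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the cohort CSV files.
#' @return A list with `patients`, `observations`, `ground_truth` data frames
#'   (and the manifest if present).
#' @export
read_cohort <- function(dir) {
  out <- list(
    patients = utils::read.csv(file.path(dir, "patients.csv"),
                               stringsAsFactors = FALSE),
    observations = utils::read.csv(file.path(dir, "observations.csv"),
                                   stringsAsFactors = FALSE),
    ground_truth = utils::read.csv(file.path(dir, "ground_truth.csv"),
                                   stringsAsFactors = FALSE))
  mf <- file.path(dir, "manifest.yaml")
  if (file.exists(mf)) out$manifest <- yaml::read_yaml(mf)
  class(out) <- "vp_cohort"
  out
}
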