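#' Default pipeline configuration
#'
#' Desk-scale defaults: a ~200-patient, 3-hospital cohort generated with the
#' 100-compartment model, matched with a 20-compartment model at 100
#' objective evaluations per patient, consensus clustering with 200 resamples
#' and quality curves over k = 2..7 with 100 subsample repeats. Every field
#' can be overridden via a YAML config file or by editing the returned list;
#' unknown keys are rejected.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    cohort = list(profiles = hospital_profiles_default(),
                  archetypes = archetype_defaults(),
                  noise_sd = noise_defaults(), p_dx = 0.6, n_comp = 100,
                  hb = 12, physio_cv = 0.10),
    model = list(n_comp = 20, tol = 1e-6, max_iter = 200, hb = 12, pb = 760,
                 ph2o = 47),
    matching = list(budget = 100, bounds = NULL),
    clustering = list(ks = 2:7, n_resamples = 200, frac = 0.8, tau = 0.5,
                      quality_repeats = 100, quality_resamples = 100,
                      k_final = 5),
    stats = list(alpha = 0.05, var_equal = FALSE)
  )
}

# merge a user config into the defaults, rejecting unknown keys
merge_config <- function(user, defaults = default_config()) {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown config key: ", key)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]) && !key %in% c("profiles", "archetypes")) {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(yaml::read_yaml(path))
}

#' ICD-code membership matrix from semicolon-joined code strings
#' @param icd_codes character vector, codes joined by ";".
#' @return Logical matrix (patients x codes).
#' @export
icd_membership <- function(icd_codes) {
  codes <- strsplit(ifelse(is.na(icd_codes), "", icd_codes), ";", fixed = TRUE)
  all_codes <- sort(unique(unlist(codes)))
  all_codes <- all_codes[all_codes != ""]
  m <- vapply(all_codes, function(cd) vapply(codes, function(v) cd %in% v,
                                             logical(1)),
              logical(length(codes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(codes),
                                   dimnames = list(NULL, all_codes))
  m
}

#' Fit the virtual-patient model to every eligible patient of a cohort
#'
#' @param prep result of [preprocess_cohort()].
#' @param config pipeline configuration (model / matching sections).
#' @param seed base seed; each patient gets a derived deterministic seed.
#' @param progress print one line per 25 patients.
#' @return A list with `fits` (per-patient summary data frame),
#'   `model_features` (matrix, acceptable patients only) and `fit_objects`.
#' @export
fit_cohort <- function(prep, config = default_config(), seed = config$seed,
                       progress = FALSE) {
  pids <- prep$eligible$patient_id
  mc <- config$model
  rows <- list(); feats <- list(); objs <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    ww <- prep$windows[[pid]]
    pseed <- (as.integer(seed) + 7919L * i) %% 2147483647L + 1L
    fit <- fit_vp(ww$w1, ww$w2, n_comp = mc$n_comp,
                  budget = config$matching$budget, seed = pseed,
                  patient_id = pid, hb = mc$hb, pb = mc$pb, ph2o = mc$ph2o)
    rows[[pid]] <- data.frame(
      patient_id = pid, obj_w1 = fit$obj_w1, obj_w2 = fit$obj_w2,
      acceptable_w1 = fit$acceptable_w1, acceptable_w2 = fit$acceptable_w2,
      ncc_w1 = fit$config_w1$n_cc, ncc_w2 = fit$ncc_w2,
      n_sim_calls = fit$n_sim_calls)
    if (fit$acceptable_w1 && fit$acceptable_w2)
      feats[[pid]] <- model_derived_features(fit, hb = mc$hb, pb = mc$pb,
                                             ph2o = mc$ph2o)
    objs[[pid]] <- fit
    if (progress && i %% 25 == 0)
      message("fitted ", i, "/", length(pids), " patients")
  }
  list(fits = do.call(rbind, rows),
       model_features = if (length(feats)) do.call(rbind, feats) else
         matrix(numeric(), 0, 0),
       fit_objects = objs)
}

# cluster one feature arm: quality curve + final consensus at k_final
.cluster_arm <- function(X, cl_cfg, seed) {
  qc <- quality_curve(X, ks = cl_cfg$ks, repeats = cl_cfg$quality_repeats,
                      frac = cl_cfg$frac,
                      n_resamples = cl_cfg$quality_resamples,
                      tau = cl_cfg$tau, seed = seed)
  final <- consensus_cluster(X, cl_cfg$k_final,
                             n_resamples = cl_cfg$n_resamples,
                             frac = cl_cfg$frac, tau = cl_cfg$tau,
                             seed = seed + 1L)
  list(quality = qc, final = final)
}

#' Run the complete analysis pipeline
#'
#' generate -> preprocess -> match -> cluster (raw and model-derived arms) ->
#' enrich -> compare, writing every artifact plus a `summary.json` into
#' `out_dir`. Identical seed and configuration give an identical summary.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param progress print stage progress messages.
#' @return The summary list, invisibly when `out_dir` is set.
#' @export
run_all <- function(config = default_config(), out_dir = NULL,
                    progress = FALSE) {
  seed <- as.integer(config$seed)
  say <- function(...) if (progress) message(...)

  say("stage 1/6: generating cohort")
  cohort <- generate_cohort(config$cohort$profiles, config$cohort$archetypes,
                            seed = seed, n_comp = config$cohort$n_comp,
                            noise_sd = config$cohort$noise_sd,
                            p_dx = config$cohort$p_dx, hb = config$cohort$hb,
                            physio_cv = config$cohort$physio_cv)

  say("stage 2/6: preprocessing")
  prep <- preprocess_cohort(cohort$patients, cohort$observations)
  if (nrow(prep$eligible) < 10)
    stop("pipeline aborted at preprocessing: fewer than 10 eligible patients")

  say("stage 3/6: matching ", nrow(prep$eligible), " patients")
  fits <- fit_cohort(prep, config, seed = seed, progress = progress)

  say("stage 4/6: clustering both arms")
  cl_cfg <- config$clustering
  X_raw <- prep$features
  X_mod <- fits$model_features
  if (nrow(X_mod) < 4 * cl_cfg$k_final)
    stop("pipeline aborted at clustering: too few acceptably fitted patients")
  arm_raw <- .cluster_arm(X_raw, cl_cfg, seed + 101L)
  arm_mod <- .cluster_arm(X_mod, cl_cfg, seed + 202L)

  say("stage 5/6: enrichment")
  alpha <- config$stats$alpha
  pat <- cohort$patients
  enr <- lapply(list(raw = list(X = X_raw, arm = arm_raw),
                     model = list(X = X_mod, arm = arm_mod)),
                function(a) {
    ids <- rownames(a$X)
    idx <- match(ids, pat$patient_id)
    list(conditions = enrich_clusters(a$arm$final$labels,
                                      icd_membership(pat$icd_codes[idx]),
                                      alpha = alpha),
         hospitals = enrich_clusters(a$arm$final$labels,
                                     pat$hospital_id[idx], alpha = alpha))
  })

  say("stage 6/6: arm comparison and summary")
  comparisons <- lapply(seq_along(cl_cfg$ks), function(j)
    compare_arms(arm_raw$quality$samples[, j], arm_mod$quality$samples[, j],
                 k = cl_cfg$ks[j], alpha = alpha,
                 var_equal = config$stats$var_equal))

  summary <- .build_summary(cohort, prep, fits, arm_raw, arm_mod, enr,
                            comparisons, config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.csv(prep$eligible, file.path(out_dir, "eligible.csv"),
                     row.names = FALSE)
    utils::write.csv(prep$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(X_raw), X_raw,
                                check.names = FALSE),
                     file.path(out_dir, "raw_features.csv"),
                     row.names = FALSE)
    utils::write.csv(fits$fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(X_mod), X_mod,
                                check.names = FALSE),
                     file.path(out_dir, "model_features.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(X_raw),
                                label = arm_raw$final$labels),
                     file.path(out_dir, "labels_raw.csv"), row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(X_mod),
                                label = arm_mod$final$labels),
                     file.path(out_dir, "labels_model.csv"),
                     row.names = FALSE)
    qq <- rbind(cbind(arm = "raw", arm_raw$quality$curve),
                cbind(arm = "model", arm_mod$quality$curve))
    utils::write.csv(qq, file.path(out_dir, "quality_curve.csv"),
                     row.names = FALSE)
    for (arm in names(enr)) {
      utils::write.csv(as.data.frame(enr[[arm]]$conditions),
                       file.path(out_dir, paste0("enrichment_", arm,
                                                 "_conditions.csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(enr[[arm]]$hospitals),
                       file.path(out_dir, paste0("enrichment_", arm,
                                                 "_hospitals.csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    grDevices::svg(file.path(out_dir, "enrichment.svg"), width = 10,
                   height = 5)
    graphics::par(mfrow = c(1, 2))
    plot_enrichment(enr$raw$conditions, enr$raw$hospitals,
                    main = "Raw charted features")
    plot_enrichment(enr$model$conditions, enr$model$hospitals,
                    main = "Model-derived features")
    grDevices::dev.off()
    grDevices::svg(file.path(out_dir, "quality.svg"), width = 6, height = 5)
    plot(arm_raw$quality, col = "darkorange",
         main = "Clustering quality by arm")
    cc <- arm_mod$quality$curve
    graphics::lines(cc$k, cc$mean, type = "b", pch = 17, col = "steelblue")
    graphics::arrows(cc$k, cc$mean - cc$ci95, cc$k, cc$mean + cc$ci95,
                     angle = 90, code = 3, length = 0.04, col = "steelblue")
    graphics::legend("bottomleft", c("raw", "model-derived"),
                     col = c("darkorange", "steelblue"), pch = c(19, 17))
    grDevices::dev.off()
    return(invisible(summary))
  }
  summary
}

.build_summary <- function(cohort, prep, fits, arm_raw, arm_mod, enr,
                           comparisons, config) {
  ff <- fits$fits
  alpha <- config$stats$alpha

  # headline bias-reduction quantities
  top_overall_is_hospital <- function(e) {
    tc <- attr(e$conditions, "top"); th <- attr(e$hospitals, "top")
    cl <- intersect(tc$cluster, th$cluster)
    hosp_top <- th$p_raw[match(cl, th$cluster)] <
      tc$p_raw[match(cl, tc$cluster)]
    sig <- th$significant[match(cl, th$cluster)]
    cl[hosp_top & sig]
  }
  max_neglog10_hosp <- function(e) max(-log10(pmax(e$hospitals$p_raw,
                                                   1e-300)))
  # model-arm diagnosed-ARDS cluster with the largest closed-compartment rise
  mod_cond <- enr$model$conditions
  j80 <- mod_cond[mod_cond$category == "J80" & mod_cond$significant, ]
  X_mod <- fits$model_features
  labels_mod <- arm_mod$final$labels
  dn_by_cl <- tapply(X_mod[, "delta_ncc"], labels_mod, mean)
  dn_by_cl <- dn_by_cl[names(dn_by_cl) != "0"]
  cl_max_dncc <- as.integer(names(which.max(dn_by_cl)))
  ards_cluster_found <- nrow(j80) > 0 && cl_max_dncc %in% j80$cluster

  k_final <- config$clustering$k_final
  list(
    seed = config$seed,
    cohort = list(n_generated = nrow(cohort$patients),
                  n_eligible = nrow(prep$eligible),
                  n_excluded = length(unique(prep$exclusions$patient_id))),
    matching = list(
      n_fitted = nrow(ff),
      acceptable_w1_rate = mean(ff$acceptable_w1),
      acceptable_w2_rate = mean(ff$acceptable_w2),
      acceptable_both = sum(ff$acceptable_w1 & ff$acceptable_w2)),
    clustering = list(
      k_final = k_final,
      mean_consensus_raw = arm_raw$final$mean_consensus,
      mean_consensus_model = arm_mod$final$mean_consensus,
      quality_raw = arm_raw$quality$curve,
      quality_model = arm_mod$quality$curve,
      outliers_raw = sum(arm_raw$final$labels == 0),
      outliers_model = sum(arm_mod$final$labels == 0)),
    enrichment = list(
      raw_clusters_top_hospital = top_overall_is_hospital(enr$raw),
      model_clusters_top_hospital = top_overall_is_hospital(enr$model),
      max_neglog10_hospital_raw = max_neglog10_hosp(enr$raw),
      max_neglog10_hospital_model = max_neglog10_hosp(enr$model),
      model_ards_cluster = if (nrow(j80)) j80$cluster else integer(),
      cluster_max_delta_ncc = cl_max_dncc),
    comparisons = lapply(comparisons, function(cmp)
      cmp[c("k", "mean_quality_raw", "mean_quality_model", "t_stat",
            "p_value", "conclusion")]),
    headline = list(
      raw_arm_hospital_driven =
        length(top_overall_is_hospital(enr$raw)) >= 1,
      model_arm_ards_cluster = ards_cluster_found,
      hospital_bias_reduced =
        max_neglog10_hosp(enr$model) < max_neglog10_hosp(enr$raw),
      model_quality_geq_raw_at_k =
        arm_mod$quality$curve$mean[arm_mod$quality$curve$k == k_final] >=
          arm_raw$quality$curve$mean[arm_raw$quality$curve$k == k_final])
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate-cohort`, `preprocess`, `fit`, `cluster`, `enrich`,
#' `run-all`; common flags `--config PATH`, `--seed INT`, `--out DIR` (plus
#' `--k INT` and `--arm raw|model` for `cluster`/`enrich`). Stage commands
#' read their inputs from a previous stage's output directory. Returns an
#' exit code instead of quitting, so wrappers decide process termination.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 2 on usage/validation errors.
#' @export
vp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: ardsvp-pipeline <simulate-cohort|preprocess|fit|cluster|enrich|run-all>",
        "[--config PATH] [--seed INT] [--out DIR] [--k INT] [--arm raw|model]\n")
    2L
  }
  if (length(args) < 1) return(usage())
  cmd <- args[1]
  if (!cmd %in% c("simulate-cohort", "preprocess", "fit", "cluster",
                  "enrich", "run-all")) return(usage())
  opts <- list(seed = NULL, config = NULL, out = "ardsvp-run", k = NULL,
               arm = "model")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!grepl("^--", args[i]) || i == length(args) ||
        !key %in% names(opts)) return(usage())
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  res <- tryCatch({
    config <- if (!is.null(opts$config)) read_config(opts$config)
              else default_config()
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (is.na(config$seed)) stop("invalid --seed")
    out <- opts$out
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    switch(cmd,
      "simulate-cohort" = {
        cohort <- generate_cohort(config$cohort$profiles,
                                  config$cohort$archetypes,
                                  seed = config$seed,
                                  n_comp = config$cohort$n_comp,
                                  noise_sd = config$cohort$noise_sd,
                                  p_dx = config$cohort$p_dx,
                                  hb = config$cohort$hb,
                                  physio_cv = config$cohort$physio_cv)
        write_cohort(cohort, file.path(out, "cohort"))
      },
      "preprocess" = {
        cohort <- read_cohort(file.path(out, "cohort"))
        prep <- preprocess_cohort(cohort$patients, cohort$observations)
        utils::write.csv(prep$eligible, file.path(out, "eligible.csv"),
                         row.names = FALSE)
        utils::write.csv(prep$exclusions, file.path(out, "exclusions.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(patient_id = rownames(prep$features),
                                    prep$features, check.names = FALSE),
                         file.path(out, "raw_features.csv"),
                         row.names = FALSE)
      },
      "fit" = {
        cohort <- read_cohort(file.path(out, "cohort"))
        prep <- preprocess_cohort(cohort$patients, cohort$observations)
        fits <- fit_cohort(prep, config, seed = config$seed)
        utils::write.csv(fits$fits, file.path(out, "fits.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(patient_id = rownames(fits$model_features),
                     fits$model_features, check.names = FALSE),
          file.path(out, "model_features.csv"), row.names = FALSE)
      },
      "cluster" = {
        k <- if (is.null(opts$k)) config$clustering$k_final
             else as.integer(opts$k)
        if (is.na(k) || k < 2) stop("validation error: k must be >= 2")
        fn <- if (opts$arm == "raw") "raw_features.csv"
              else "model_features.csv"
        X <- utils::read.csv(file.path(out, fn), check.names = FALSE)
        rn <- X$patient_id
        X <- as.matrix(X[, -1, drop = FALSE]); rownames(X) <- rn
        res <- consensus_cluster(X, k,
                                 n_resamples = config$clustering$n_resamples,
                                 frac = config$clustering$frac,
                                 tau = config$clustering$tau,
                                 seed = config$seed)
        utils::write.csv(data.frame(patient_id = rn, label = res$labels),
                         file.path(out, paste0("labels_", opts$arm, ".csv")),
                         row.names = FALSE)
      },
      "enrich" = {
        lab <- utils::read.csv(file.path(out, paste0("labels_", opts$arm,
                                                     ".csv")))
        cohort <- read_cohort(file.path(out, "cohort"))
        idx <- match(lab$patient_id, cohort$patients$patient_id)
        e1 <- enrich_clusters(lab$label,
                              icd_membership(cohort$patients$icd_codes[idx]),
                              alpha = config$stats$alpha)
        e2 <- enrich_clusters(lab$label, cohort$patients$hospital_id[idx],
                              alpha = config$stats$alpha)
        utils::write.csv(as.data.frame(e1),
                         file.path(out, paste0("enrichment_", opts$arm,
                                               "_conditions.csv")),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(e2),
                         file.path(out, paste0("enrichment_", opts$arm,
                                               "_hospitals.csv")),
                         row.names = FALSE)
      },
      "run-all" = run_all(config, out_dir = out)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  res
}

#' Parameter-recovery experiment against the generator's ground truth
#'
#' Generates a small single-hospital cohort with all hospital effects zeroed
#' and optional zero noise, fits every patient in the ground-truth analysis
#' windows, and reports per-patient recovery errors for the anatomical shunt
#' fraction, the window-2 closed-compartment count (expressed per 100
#' compartments) and the metabolic O2 consumption, plus the acceptable-fit
#' indicators.
#'
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @param noise_sd measurement-noise SDs (default zero: noise-free).
#' @param n_comp compartments used for both generation and matching.
#' @param budget window-1 optimizer budget.
#' @return A data frame with one row per fitted patient.
#' @export
recovery_experiment <- function(n_patients = 20, seed = 1,
                                noise_sd = c(pao2 = 0, paco2 = 0, ph = 0,
                                             sao2 = 0, pinsp = 0),
                                n_comp = 20, budget = 100, physio_cv = 0) {
  prof <- list(list(
    hospital_id = "HospSim", n_patients = n_patients, pao2_bias = 0,
    peep_offset = 0, fio2_rounding = 0, charting_interval = 4, vt_per_kg = 7,
    archetype_mix = c(ards = 0.5, cardiac = 0.2, copd_like = 0.2,
                      control = 0.1)),
    list(hospital_id = "HospSim2", n_patients = 1, pao2_bias = 0,
         peep_offset = 0, fio2_rounding = 0, charting_interval = 4,
         vt_per_kg = 7, archetype_mix = c(ards = 1)))
  cohort <- generate_cohort(prof, seed = seed, n_comp = n_comp,
                            noise_sd = noise_sd, physio_cv = physio_cv)
  gt <- cohort$ground_truth[seq_len(n_patients), ]
  wide <- pivot_observations(cohort$observations)
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    pid <- gt$patient_id[i]
    w <- wide[wide$patient_id == pid, , drop = FALSE]
    ww <- extract_windows(w, gt$t0[i])
    if (!ww$eligible) next
    fit <- fit_vp(ww$w1, ww$w2, n_comp = n_comp, budget = budget,
                  seed = (seed + 31L * i) %% 2147483647L + 1L,
                  patient_id = pid)
    rows[[pid]] <- data.frame(
      patient_id = pid, archetype = gt$archetype[i],
      fs_anat_true = gt$fs_anat[i], fs_anat_hat = fit$config_w1$fs_anat,
      fs_anat_err = abs(fit$config_w1$fs_anat - gt$fs_anat[i]),
      ncc_w2_true = gt$ncc_w2[i], ncc_w2_hat = fit$ncc_w2,
      ncc_w2_err_per100 = abs(fit$ncc_w2 - gt$ncc_w2[i]) * 100 / n_comp,
      vo2_true = gt$vo2[i], vo2_hat = fit$config_w1$vo2,
      vo2_rel_err = abs(fit$config_w1$vo2 - gt$vo2[i]) / gt$vo2[i],
      acceptable_w1 = fit$acceptable_w1, acceptable_w2 = fit$acceptable_w2,
      obj_w1 = fit$obj_w1, obj_w2 = fit$obj_w2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
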