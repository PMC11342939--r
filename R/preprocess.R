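#' Pivot long-format observations to one row per charting time
#'
#' @param observations long data frame with `patient_id`, `time_h`,
#'   `variable`, `value`.
#' @return Wide data frame ordered by patient and time, one column per
#'   charted variable.
#' @export
pivot_observations <- function(observations) {
  stopifnot(all(c("patient_id", "time_h", "variable", "value") %in%
                  names(observations)))
  out <- unique(observations[c("patient_id", "time_h")])
  out <- out[order(out$patient_id, out$time_h), , drop = FALSE]
  rk <- paste(out$patient_id, out$time_h)
  for (v in sort(unique(observations$variable))) {
    sub <- observations[observations$variable == v, ]
    out[[v]] <- sub$value[match(rk, paste(sub$patient_id, sub$time_h))]
  }
  rownames(out) <- NULL
  out
}

#' Apply the study inclusion criteria
#'
#' Keeps adult patients (lower bound of the age bin at least 18 years) with a
#' cumulative invasive mechanical-ventilation duration of at least 24 hours
#' (boundary inclusive). Records with missing `mv_hours` are skipped with a
#' warning. Input order is preserved.
#'
#' @param patients data frame with `age_bin` and `mv_hours` columns.
#' @return The eligible subset of `patients`.
#' @export
apply_inclusion_criteria <- function(patients) {
  if (nrow(patients) == 0) return(patients)
  missing_mv <- is.na(patients$mv_hours)
  if (any(missing_mv))
    warning(sum(missing_mv), " record(s) skipped: missing mv_hours")
  age_lo <- as.numeric(sub("^\\[([0-9.]+),.*$", "\\1", patients$age_bin))
  keep <- !missing_mv & patients$mv_hours >= 24 & !is.na(age_lo) &
    age_lo >= 18
  patients[keep, , drop = FALSE]
}

#' k-anonymity exclusion filter on binned biometric variables
#'
#' Two exclusion rules, both decided in a single pass on the original counts
#' and then unioned (which makes the filter idempotent): all patients of any
#' interval holding fewer than `k_interval` patients are excluded, and all
#' patients of any non-empty combination cell (across the four binned
#' variables) holding fewer than `k_cell` patients are excluded -- those are
#' the patients whose attribute combination is re-identifiable. Empty
#' combination cells pose no re-identification risk and are ignored.
#'
#' @param patients data frame with the binned variables.
#' @param binned_vars names of the binned columns.
#' @param k_interval minimum per-interval count (default 8).
#' @param k_cell minimum per-combination-cell count (default 10).
#' @return A list with `retained` (data frame), `excluded` (data frame) and
#'   `report` (one row per excluded patient: `patient_id`, `rule`, `detail`).
#' @export
k_anonymity_filter <- function(patients,
                               binned_vars = c("age_bin", "height_bin",
                                               "weight_bin", "bmi_bin"),
                               k_interval = 8, k_cell = 10) {
  n <- nrow(patients)
  if (n == 0)
    return(list(retained = patients, excluded = patients,
                report = data.frame(patient_id = character(),
                                    rule = character(),
                                    detail = character())))
  cell <- do.call(paste, c(patients[binned_vars], sep = "|"))
  cell_counts <- table(cell)

  excl <- rep(FALSE, n)
  report <- list()
  for (v in binned_vars) {
    lev_counts <- table(patients[[v]])
    for (lev in names(lev_counts)) {
      if (lev_counts[[lev]] >= k_interval) next
      in_lev <- patients[[v]] == lev
      excl <- excl | in_lev
      report[[length(report) + 1L]] <- data.frame(
        patient_id = patients$patient_id[in_lev],
        rule = "k_anonymity",
        detail = sprintf("interval %s=%s has %d < %d patients",
                         v, lev, lev_counts[[lev]], k_interval))
    }
  }
  for (cl in names(cell_counts)) {
    if (cell_counts[[cl]] >= k_cell) next
    in_cell <- cell == cl
    excl <- excl | in_cell
    report[[length(report) + 1L]] <- data.frame(
      patient_id = patients$patient_id[in_cell],
      rule = "k_anonymity",
      detail = sprintf("combination cell %s has %d < %d patients",
                       cl, cell_counts[[cl]], k_cell))
  }
  report <- if (length(report)) unique(do.call(rbind, report)) else
    data.frame(patient_id = character(), rule = character(),
               detail = character())
  rownames(report) <- NULL
  list(retained = patients[!excl, , drop = FALSE],
       excluded = patients[excl, , drop = FALSE],
       report = report)
}

#' Detect the suspected ARDS onset from the P/F (Horovitz) time series
#'
#' Returns the earliest charted time at which the PaO2/FiO2 ratio drops below
#' `threshold` (300 mmHg) and stays below it for at least `sustain_h` hours:
#' every subsequent charted value within that horizon must be below the
#' threshold, the below-threshold observations must span the full horizon,
#' and (last observation carried forward between charted rows) gaps longer
#' than `max_gap_h` break sustainment.
#'
#' @param bga data frame with columns `time_h`, `pao2`, `fio2` (charted).
#' @param threshold P/F threshold in mmHg (default 300).
#' @param sustain_h required sustainment horizon in hours (default 24).
#' @param max_gap_h maximum charting gap compatible with carrying the last
#'   observation forward (default 12).
#' @return The onset time in hours, or `NA` if no qualifying time exists.
#' @export
detect_suspected_onset <- function(bga, threshold = 300, sustain_h = 24,
                                   max_gap_h = 12) {
  bga <- bga[!is.na(bga$pao2) & !is.na(bga$fio2), , drop = FALSE]
  if (nrow(bga) < 2) stop("insufficient data: fewer than 2 charted P/F rows")
  bga <- bga[order(bga$time_h), , drop = FALSE]
  tt <- bga$time_h
  below <- (bga$pao2 / bga$fio2) < threshold

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_id <- rep(seq_along(r$lengths), r$lengths)
  # every below-threshold row is a candidate onset (sustainment can begin
  # mid-run, e.g. after a charting gap breaks it at the run's first row)
  for (s in which(below)) {
    e <- ends[run_id[s]]  # last below-threshold row of this run
    t0 <- tt[s]
    horizon <- t0 + sustain_h
    # span: the run itself must reach the horizon (data after the run, if
    # any, is above threshold and would have to lie beyond the horizon)
    if (tt[e] < horizon) next
    if (e < nrow(bga) && tt[e + 1L] <= horizon) next  # above-threshold row inside
    in_h <- s:e
    in_h <- in_h[tt[in_h] <= horizon]
    if (length(in_h) > 1 && max(diff(tt[in_h])) > max_gap_h) next
    if (horizon - max(tt[in_h]) > max_gap_h) next
    return(t0)
  }
  NA_real_
}

#' Extract the two analysis windows around the suspected onset
#'
#' Window 1 is `[t0 - 48h, t0 - 24h)` and window 2 is `[t0, t0 + 24h)`, both
#' half-open; the 24 h between them is a transient and is excluded. A patient
#' is eligible only with at least one blood-gas row in each window.
#'
#' @param obs_wide wide observation data frame for one patient (see
#'   [pivot_observations()]).
#' @param t0 onset time (hours from admission); must be at least 48.
#' @return A list with `t0`, data frames `w1` and `w2`, a logical `eligible`
#'   and a `reason` string when ineligible.
#' @export
extract_windows <- function(obs_wide, t0) {
  if (t0 < 48) stop("window underflow: t0 earlier than 48 h")
  tt <- obs_wide$time_h
  w1 <- obs_wide[tt >= t0 - 48 & tt < t0 - 24, , drop = FALSE]
  w2 <- obs_wide[tt >= t0 & tt < t0 + 24, , drop = FALSE]
  has_bga <- function(w) nrow(w) > 0 && any(!is.na(w$pao2))
  eligible <- has_bga(w1) && has_bga(w2)
  reason <- if (eligible) NA_character_
    else if (!has_bga(w1)) "no blood gas in window 1"
    else "no blood gas in window 2"
  list(t0 = t0, w1 = w1, w2 = w2, eligible = eligible, reason = reason)
}

#' Raw (charted) feature vector of a patient
#'
#' Per-variable arithmetic means within each analysis window for the ten
#' routinely charted variables, giving 20 features named `<variable>@w1` /
#' `<variable>@w2`.
#'
#' @param w1,w2 wide per-window observation data frames.
#' @param vars charted variables to average.
#' @return A list with `values` (named numeric vector of length
#'   `2 * length(vars)`), `complete` (logical) and `missing_vars`.
#' @export
raw_features <- function(w1, w2,
                         vars = c("pao2", "paco2", "ph", "sao2", "fio2",
                                  "peep", "vt", "rr", "pinsp", "hr")) {
  vals <- c()
  missing <- character()
  for (wname in c("w1", "w2")) {
    w <- if (wname == "w1") w1 else w2
    for (v in vars) {
      x <- if (v %in% names(w)) w[[v]] else NA_real_
      m <- mean(x, na.rm = TRUE)
      if (!is.finite(m)) missing <- c(missing, paste0(v, "@", wname))
      vals[paste0(v, "@", wname)] <- m
    }
  }
  list(values = vals, complete = length(missing) == 0,
       missing_vars = missing)
}

#' Full preprocessing of a cohort
#'
#' Applies, in order: inclusion criteria, the k-anonymity filter, suspected
#' onset detection on the charted P/F series, analysis-window extraction and
#' raw-feature construction. Patients failing any step are reported in
#' `exclusions` with a reason; nothing is dropped silently.
#'
#' @param patients patient-level data frame (see [generate_cohort()]).
#' @param observations long observation data frame.
#' @param ... passed to [detect_suspected_onset()].
#' @return A list with `eligible` (data frame `patient_id`, `t0`),
#'   `features` (numeric matrix of raw features, rows named by patient),
#'   `windows` (named list of window pairs) and `exclusions` (data frame).
#' @export
preprocess_cohort <- function(patients, observations, ...) {
  excl <- list()
  note <- function(ids, rule, detail) {
    if (length(ids))
      excl[[length(excl) + 1L]] <<- data.frame(patient_id = ids, rule = rule,
                                               detail = detail)
  }

  inc <- apply_inclusion_criteria(patients)
  note(setdiff(patients$patient_id, inc$patient_id), "inclusion",
       "age below 18 or invasive MV under 24 h")
  ka <- k_anonymity_filter(inc)
  if (nrow(ka$report)) excl[[length(excl) + 1L]] <- ka$report
  kept <- ka$retained

  wide <- pivot_observations(
    observations[observations$patient_id %in% kept$patient_id, , drop = FALSE])
  by_pid <- split(wide, wide$patient_id)

  elig <- list(); feats <- list(); wins <- list()
  for (pid in kept$patient_id) {
    w <- by_pid[[pid]]
    if (is.null(w)) { note(pid, "onset", "no observations"); next }
    t0 <- tryCatch(
      detect_suspected_onset(w[c("time_h", "pao2", "fio2")], ...),
      error = function(e) conditionMessage(e))
    if (is.character(t0)) { note(pid, "onset", t0); next }
    if (is.na(t0)) { note(pid, "onset", "no sustained P/F below 300"); next }
    if (t0 < 48) { note(pid, "onset", "window underflow: onset before 48 h"); next }
    ww <- extract_windows(w, t0)
    if (!ww$eligible) { note(pid, "windows", ww$reason); next }
    rf <- raw_features(ww$w1, ww$w2)
    if (!rf$complete) {
      note(pid, "features", paste("missing:", paste(rf$missing_vars,
                                                    collapse = ", ")))
      next
    }
    elig[[pid]] <- data.frame(patient_id = pid, t0 = t0)
    feats[[pid]] <- rf$values
    wins[[pid]] <- ww
  }

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), rule = character(),
               detail = character())
  rownames(exclusions) <- NULL
  features <- if (length(feats)) do.call(rbind, feats) else
    matrix(numeric(), 0, 0)
  list(eligible = if (length(elig)) do.call(rbind, elig) else
         data.frame(patient_id = character(), t0 = numeric()),
       features = features, windows = wins, exclusions = exclusions)
}
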