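# Independent brute-force oracles used to verify the package's statistics.

# Consensus matrix by exhaustive pair loops over the resampled partitions.
oracle_consensus_matrix <- function(partitions, N) {
  D <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    m <- 0; cnt <- 0
    for (p in partitions) {
      pi <- match(i, p$idx); pj <- match(j, p$idx)
      if (!is.na(pi) && !is.na(pj)) {
        cnt <- cnt + 1
        if (p$labels[pi] == p$labels[pj]) m <- m + 1
      }
    }
    D[i, j] <- if (cnt > 0) m / cnt else 0
  }
  D
}

# Cluster consensus by explicit pair enumeration.
oracle_cluster_consensus <- function(D, labels) {
  ks <- sort(unique(labels[labels > 0]))
  m_k <- sapply(ks, function(kk) {
    idx <- which(labels == kk)
    if (length(idx) < 2) return(1)
    tot <- 0; cnt <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
      tot <- tot + D[idx[a], idx[b]]; cnt <- cnt + 1
    }
    tot / cnt
  })
  list(m_k = m_k, mean_consensus = mean(m_k))
}

# Upper-tail hypergeometric probability by exhaustive subset enumeration:
# fraction of all size-n subsets of a population with K marked items that
# contain at least k_obs marked items.
oracle_hypergeom_upper <- function(N, K, n, k_obs) {
  pop <- c(rep(1, K), rep(0, N - K))
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(pop[s]) >= k_obs)
  mean(hits)
}

# random resampled partitions for oracle-equivalence tests
random_partitions <- function(N, n_resamples, k = 2, frac = 0.8) {
  lapply(seq_len(n_resamples), function(h) {
    idx <- sort(sample.int(N, ceiling(frac * N)))
    list(idx = idx, labels = sample.int(k, length(idx), replace = TRUE))
  })
}

# small wide-format observation window for matching tests
toy_window <- function(n_rows = 4, fio2 = 0.4, vt = 500, rr = 16, hr = 80,
                       config = vp_config(fs_anat = 0.05, n_cc = 2),
                       n_comp = 20, jitter_inputs = TRUE) {
  rows <- lapply(seq_len(n_rows), function(i) {
    f <- fio2 + if (jitter_inputs) 0.05 * ((i %% 2) == 0) else 0
    r <- rr + if (jitter_inputs) 2 * (i %% 3 - 1) else 0
    s <- simulate_gas_exchange(config,
      vent_inputs(fio2 = f, vt = vt, rr = r, hr = hr), n_comp = n_comp)
    data.frame(time_h = i * 2, pao2 = s$pao2, paco2 = s$paco2,
               sao2 = s$sao2, ph = s$ph, fio2 = f, vt = vt, rr = r, hr = hr)
  })
  do.call(rbind, rows)
}

# noise-free single-hospital profiles for generator-based tests
quiet_profiles <- function(n1 = 10, n2 = 5, interval = 4,
                           mix = c(ards = 0.5, cardiac = 0.2,
                                   copd_like = 0.2, control = 0.1)) {
  list(
    list(hospital_id = "HospX", n_patients = n1, pao2_bias = 0,
         peep_offset = 0, fio2_rounding = 0, charting_interval = interval,
         vt_per_kg = 7, archetype_mix = mix),
    list(hospital_id = "HospY", n_patients = n2, pao2_bias = 0,
         peep_offset = 0, fio2_rounding = 0, charting_interval = interval,
         vt_per_kg = 7, archetype_mix = mix))
}

zero_noise <- c(pao2 = 0, paco2 = 0, ph = 0, sao2 = 0, pinsp = 0)
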