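#' Repeated k-means partitions of resampled data
#'
#' Each resample draws `ceiling(frac * N)` items without replacement and runs
#' a single k-means (random initialization) on the subsample. All randomness
#' is driven by `seed`.
#'
#' @param X numeric matrix (items x features), typically z-scored.
#' @param k number of clusters (at least 2).
#' @param n_resamples number of resamples (default 1000).
#' @param frac subsampling fraction in (0, 1] (default 0.8).
#' @param seed integer seed.
#' @param iter_max k-means iteration cap.
#' @return A list of length `n_resamples`; each element has `idx` (sampled
#'   item indices) and `labels` (cluster assignment per sampled item).
#' @export
resample_partitions <- function(X, k, n_resamples = 1000, frac = 0.8,
                                seed = 1, iter_max = 300) {
  X <- as.matrix(X)
  N <- nrow(X)
  stopifnot(k >= 2, frac > 0, frac <= 1)
  m <- ceiling(frac * N)
  if (k > m) stop("k exceeds the subsample size")
  with_seed(seed, {
    lapply(seq_len(n_resamples), function(h) {
      idx <- sort(sample.int(N, m))
      km <- NULL
      for (try in 1:5) {  # rare degenerate random inits; retry deterministically
        km <- tryCatch(
          suppressWarnings(stats::kmeans(X[idx, , drop = FALSE], centers = k,
                                         iter.max = iter_max, nstart = 1)),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) stop("k-means failed on a resample")
      list(idx = idx, labels = km$cluster)
    })
  })
}

#' Consensus matrix from resampled partitions
#'
#' Entry (i, j) is the number of resamples in which items i and j were
#' assigned to the same cluster, divided by the number of resamples in which
#' both items were sampled. Pairs never co-sampled are undefined: they are
#' stored as 0 and flagged in the `never_cosampled` attribute.
#'
#' @param partitions list produced by [resample_partitions()].
#' @param N total number of items.
#' @return N x N symmetric matrix with entries in `[0, 1]`, with attributes
#'   `M_sum` (co-cluster tallies), `I_sum` (co-sample tallies) and
#'   `never_cosampled`.
#' @export
consensus_matrix <- function(partitions, N) {
  stopifnot(length(partitions) >= 1)
  M <- matrix(0, N, N)
  I <- matrix(0, N, N)
  for (p in partitions) {
    idx <- p$idx
    I[idx, idx] <- I[idx, idx] + 1
    co <- outer(p$labels, p$labels, "==")
    M[idx, idx] <- M[idx, idx] + co
  }
  D <- matrix(0, N, N)
  pos <- I > 0
  D[pos] <- M[pos] / I[pos]
  attr(D, "M_sum") <- M
  attr(D, "I_sum") <- I
  attr(D, "never_cosampled") <- !pos
  D
}

# Average-linkage agglomeration of a dissimilarity matrix down to k groups.
# Ties in the minimum dissimilarity are broken deterministically: prefer the
# merge producing the smaller group, then the lexicographically first pair.
# (Tie order in stats::hclust is implementation-defined, which would make
# consensus partitions on tied consensus structures irreproducible.)
.avg_linkage_cut <- function(d, k) {
  N <- nrow(d)
  stopifnot(k >= 1, k <= N)
  active <- seq_len(N)
  size <- rep(1L, N)
  labels <- seq_len(N)
  diag(d) <- Inf
  while (length(active) > k) {
    da <- d[active, active, drop = FALSE]
    mn <- min(da)
    hits <- which(da - mn <= 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    msize <- size[active[hits[, 1]]] + size[active[hits[, 2]]]
    hits <- hits[order(msize, hits[, 1], hits[, 2]), , drop = FALSE]
    i <- active[hits[1, 1]]; j <- active[hits[1, 2]]
    # Lance-Williams average-linkage update onto i
    others <- setdiff(active, c(i, j))
    d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
      (size[i] + size[j])
    d[others, i] <- d[i, others]
    size[i] <- size[i] + size[j]
    labels[labels == j] <- i
    active <- setdiff(active, j)
  }
  match(labels, sort(unique(labels)))
}

#' Final consensus partition with outlier labelling
#'
#' Average-linkage hierarchical clustering on the consensus dissimilarity
#' `1 - D`, cut at `k` clusters (with a deterministic smallest-merge-first
#' tie-break). An item that cannot be securely assigned --
#' mean consensus with the other members of its own cluster below `tau` --
#' receives the outlier label `0`. Outlier decisions are made simultaneously
#' on the initial cut.
#'
#' @param D consensus matrix.
#' @param k number of clusters.
#' @param tau consensus threshold below which an item is an outlier
#'   (default 0.5).
#' @return Integer labels of length `nrow(D)`; `0` marks outliers.
#' @export
final_partition <- function(D, k, tau = 0.5) {
  N <- nrow(D)
  labels <- .avg_linkage_cut(1 - D, k)
  out <- labels
  for (i in seq_len(N)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) > 0 && mean(D[i, own]) < tau) out[i] <- 0L
  }
  if (all(out == 0L)) stop("degenerate result: all items labelled outliers")
  out
}

#' Cluster consensus m(k) and mean cluster consensus
#'
#' A cluster's consensus is the average consensus index over all unordered
#' pairs of items in the cluster; the mean cluster consensus is the
#' unweighted average over clusters. Outliers (label 0) are excluded;
#' singleton clusters get consensus 1 by convention.
#'
#' @param D consensus matrix.
#' @param labels integer labels (`0` = outlier).
#' @return A list with `m_k` (named per-cluster consensus) and
#'   `mean_consensus`.
#' @export
cluster_consensus <- function(D, labels) {
  ks <- sort(unique(labels[labels > 0]))
  if (length(ks) == 0) stop("no non-outlier clusters")
  m_k <- vapply(ks, function(kk) {
    idx <- which(labels == kk)
    if (length(idx) < 2) return(1)
    pairs <- D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
    mean(pairs)
  }, numeric(1))
  names(m_k) <- ks
  list(m_k = m_k, mean_consensus = mean(m_k))
}

#' Consensus k-means clustering of a feature matrix
#'
#' The full procedure: resampled k-means partitions, the consensus matrix,
#' the final average-linkage partition with outlier labelling, and the
#' consensus quality statistics.
#'
#' @param X numeric matrix (items x features); z-scored per feature unless
#'   `scale = FALSE`.
#' @param k number of clusters.
#' @param n_resamples resampling repetitions (default 1000).
#' @param frac subsample fraction (default 0.8).
#' @param tau outlier consensus threshold (default 0.5).
#' @param seed integer seed.
#' @param scale z-score columns first (default TRUE).
#' @return An object of class `consensus_result`: `D`, `labels` (0 =
#'   outlier), `m_k`, `mean_consensus`, `k`, `n_resamples`.
#' @export
consensus_cluster <- function(X, k, n_resamples = 1000, frac = 0.8,
                              tau = 0.5, seed = 1, scale = TRUE) {
  X <- as.matrix(X)
  if (scale) X <- zscore(X)
  parts <- resample_partitions(X, k, n_resamples = n_resamples, frac = frac,
                               seed = seed)
  D <- consensus_matrix(parts, nrow(X))
  labels <- final_partition(D, k, tau = tau)
  cc <- cluster_consensus(D, labels)
  structure(list(D = D, labels = labels, m_k = cc$m_k,
                 mean_consensus = cc$mean_consensus, k = k,
                 n_resamples = n_resamples, frac = frac, tau = tau,
                 items = rownames(X)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus k-means: k = %d, %d resamples, %d items (%d outliers)\n",
              x$k, x$n_resamples, length(x$labels), sum(x$labels == 0)))
  cat("  cluster sizes: ",
      paste(table(x$labels[x$labels > 0]), collapse = ", "), "\n")
  cat("  cluster consensus m(k): ",
      paste(sprintf("%.3f", x$m_k), collapse = ", "), "\n")
  cat(sprintf("  mean cluster consensus: %.3f\n", x$mean_consensus))
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  ord <- order(x$labels, -rowSums(x$D))
  graphics::image(x$D[ord, ord], axes = FALSE, useRaster = TRUE,
                  main = sprintf("Consensus matrix (k = %d)", x$k),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE), ...)
  invisible(x)
}

#' Clustering-quality curve over a range of cluster counts
#'
#' For each k, the full consensus procedure is repeated `repeats` times on
#' independent subsamples of `frac` of the items and the mean cluster
#' consensus of each repeat is recorded; the curve reports the mean with a
#' 95% normal confidence interval.
#'
#' @param X numeric matrix (items x features).
#' @param ks integer vector of cluster counts (within 2..10).
#' @param repeats independent subsample repeats per k (default 100).
#' @param frac subsample fraction for the repeats (default 0.8).
#' @param n_resamples resamples inside each consensus run (default 100,
#'   a desk-scale setting).
#' @param tau outlier threshold.
#' @param seed integer seed.
#' @param scale z-score features first.
#' @return An object of class `quality_curve`: data frame `curve` (k, mean,
#'   half-width ci95) and matrix `samples` (repeats x k).
#' @export
quality_curve <- function(X, ks = 2:7, repeats = 100, frac = 0.8,
                          n_resamples = 100, tau = 0.5, seed = 1,
                          scale = TRUE) {
  stopifnot(all(ks >= 2), all(ks <= 10))
  X <- as.matrix(X)
  if (scale) X <- zscore(X)
  N <- nrow(X)
  m <- ceiling(frac * N)
  samples <- matrix(NA_real_, repeats, length(ks),
                    dimnames = list(NULL, paste0("k", ks)))
  with_seed(seed, {
    sub_seeds <- matrix(sample.int(.Machine$integer.max,
                                   repeats * length(ks)),
                        repeats, length(ks))
    for (j in seq_along(ks)) {
      for (r in seq_len(repeats)) {
        idx <- sort(sample.int(N, m))
        res <- tryCatch(
          consensus_cluster(X[idx, , drop = FALSE], ks[j],
                            n_resamples = n_resamples, frac = frac,
                            tau = tau, seed = sub_seeds[r, j],
                            scale = FALSE),
          error = function(e) NULL)
        samples[r, j] <- if (is.null(res)) NA_real_ else res$mean_consensus
      }
    }
  })
  mu <- colMeans(samples, na.rm = TRUE)
  se <- apply(samples, 2, function(v) stats::sd(v, na.rm = TRUE) /
                sqrt(sum(is.finite(v))))
  structure(list(curve = data.frame(k = ks, mean = mu, ci95 = 1.96 * se),
                 samples = samples, repeats = repeats, frac = frac),
            class = "quality_curve")
}

#' @export
print.quality_curve <- function(x, ...) {
  cat("Consensus clustering quality (mean cluster consensus +/- 95% CI)\n")
  cc <- x$curve
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  k = %d: %.3f +/- %.3f\n", cc$k[i], cc$mean[i], cc$ci95[i]))
  invisible(x)
}

#' @export
plot.quality_curve <- function(x, ...) {
  cc <- x$curve
  graphics::plot(cc$k, cc$mean, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "number of clusters k",
                 ylab = "mean cluster consensus", ...)
  graphics::arrows(cc$k, cc$mean - cc$ci95, cc$k, cc$mean + cc$ci95,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
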