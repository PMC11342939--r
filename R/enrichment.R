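#' Upper-tail (one-sided) hypergeometric probability
#'
#' `P(X >= k_obs)` for X hypergeometric: a population of `N` items contains
#' `K` of a category; `n` items are drawn (the cluster); `k_obs` of them are
#' in the category. The over-representation p-value of the category in the
#' cluster, evaluated stably on the log scale.
#'
#' @param N population size.
#' @param K category count in the population.
#' @param n cluster (sample) size.
#' @param k_obs category count observed in the cluster.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k_obs) {
  if (any(c(N, K, n, k_obs) < 0) || K > N || n > N ||
      k_obs > min(K, n) || k_obs < max(0, n - (N - K)))
    stop("inconsistent hypergeometric counts")
  if (k_obs == 0) return(1)
  stats::phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1, original order).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of clusters for categories
#'
#' Tests every (cluster, category) pair for over-representation with the
#' one-sided hypergeometric test; outlier items (label 0) are excluded from
#' both the population and the clusters. The Benjamini-Hochberg correction is
#' applied across all tests of the family (i.e. within one call).
#'
#' @param labels integer cluster labels (0 = outlier), one per item.
#' @param membership either a factor/character vector (one category per
#'   item, e.g. hospital of origin) or a logical matrix items x categories
#'   (e.g. ICD-code indicators, where an item may carry several codes).
#' @param alpha significance level (default 0.05).
#' @return A data frame of class `enrichment_result` with columns
#'   `cluster`, `category`, `N`, `K`, `n`, `k_obs`, `p_raw`, `p_adj`,
#'   `significant`, plus an attribute `top` giving each cluster's most
#'   significant category.
#' @export
enrich_clusters <- function(labels, membership, alpha = 0.05) {
  keep <- labels > 0
  labels <- labels[keep]
  if (is.matrix(membership) || is.data.frame(membership)) {
    mem <- as.matrix(membership)[keep, , drop = FALSE]
    mem <- mem != 0
  } else {
    f <- factor(membership[keep])
    mem <- vapply(levels(f), function(l) f == l,
                  logical(length(f)))
    colnames(mem) <- levels(f)
  }
  N <- length(labels)
  rows <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    n <- sum(in_cl)
    if (n == 0) { warning("empty cluster ", cl, " skipped"); next }
    for (cat_name in colnames(mem)) {
      K <- sum(mem[, cat_name])
      k_obs <- sum(mem[in_cl, cat_name])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, category = cat_name, N = N, K = K, n = n,
        k_obs = k_obs, p_raw = hypergeom_upper(N, K, n, k_obs))
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  top <- do.call(rbind, lapply(split(out, out$cluster), function(d) {
    d[order(d$p_raw, d$category), ][1, c("cluster", "category", "p_raw",
                                         "p_adj", "significant")]
  }))
  rownames(top) <- NULL
  attr(out, "top") <- top
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Compare clustering-quality distributions between two feature arms
#'
#' Two-sample two-tailed t-test (Welch by default; the equal-variance
#' Student variant is available) on the per-repeat mean-cluster-consensus
#' samples of the two arms at one cluster count.
#'
#' @param quality_raw,quality_model numeric vectors of quality samples.
#' @param k the cluster count being compared (metadata).
#' @param alpha significance level.
#' @param var_equal use the classical equal-variance Student t-test.
#' @return A list of class `arm_comparison` with means, `t_stat`, `p_value`
#'   and a `conclusion` string.
#' @export
compare_arms <- function(quality_raw, quality_model, k = NA_integer_,
                         alpha = 0.05, var_equal = FALSE) {
  quality_raw <- quality_raw[is.finite(quality_raw)]
  quality_model <- quality_model[is.finite(quality_model)]
  stopifnot(length(quality_raw) >= 2, length(quality_model) >= 2)
  if (stats::sd(quality_raw) == 0 && stats::sd(quality_model) == 0 &&
      mean(quality_raw) == mean(quality_model)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(quality_model, quality_raw, var.equal = var_equal)
  }
  p <- tt$p.value
  mr <- mean(quality_raw); mm <- mean(quality_model)
  concl <- if (p >= alpha) "no significant difference"
    else if (mm > mr) "model-derived arm higher" else "raw arm higher"
  structure(list(k = k, mean_quality_raw = mr, mean_quality_model = mm,
                 t_stat = unname(tt$statistic), p_value = p,
                 conclusion = concl, alpha = alpha,
                 var_equal = var_equal),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("Arm comparison%s: raw %.3f vs model %.3f (t = %.2f, p = %.3g): %s\n",
              if (is.na(x$k)) "" else sprintf(" at k = %d", x$k),
              x$mean_quality_raw, x$mean_quality_model, x$t_stat, x$p_value,
              x$conclusion))
  invisible(x)
}

#' Paired bar chart of the strongest condition vs hospital enrichment
#'
#' For each cluster, plots `-log10` of the most significant condition
#' enrichment next to the most significant hospital enrichment, the usual
#' display for judging whether clusters are driven by medicine or by data
#' origin.
#'
#' @param enrich_conditions,enrich_hospitals `enrichment_result` objects.
#' @param main plot title.
#' @return The matrix of plotted values, invisibly.
#' @export
plot_enrichment <- function(enrich_conditions, enrich_hospitals,
                            main = "Top enrichment per cluster") {
  topc <- attr(enrich_conditions, "top")
  toph <- attr(enrich_hospitals, "top")
  cl <- sort(union(topc$cluster, toph$cluster))
  m <- rbind(condition = -log10(topc$p_raw[match(cl, topc$cluster)]),
             hospital = -log10(toph$p_raw[match(cl, toph$cluster)]))
  colnames(m) <- paste("cluster", cl)
  graphics::barplot(m, beside = TRUE, col = c("forestgreen", "firebrick"),
                    ylab = "-log10 enrichment p-value", main = main,
                    legend.text = c("top condition", "top hospital"))
  invisible(m)
}
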