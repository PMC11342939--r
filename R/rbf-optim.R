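#' Surrogate-based derivative-free global optimization over a box
#'
#' Minimizes an expensive black-box function with a cubic radial-basis-function
#' (RBF) surrogate: a space-filling Latin hypercube design is evaluated first,
#' then each iteration interpolates all evaluated points with a cubic RBF plus
#' linear polynomial tail and picks the next evaluation from a candidate set
#' scored by a weighted combination of predicted value and distance to already
#' evaluated points. The surrogate weight cycles from exploratory to greedy,
#' the usual global/local balance for candidate-point RBF methods. All
#' randomness (design, candidates) is driven by `seed`, so the result is
#' deterministic for fixed inputs.
#'
#' @param fn objective taking a numeric vector of length `length(lower)`.
#' @param lower,upper box bounds (numeric vectors of equal length).
#' @param budget total number of objective evaluations (design included).
#' @param seed integer seed controlling all randomness.
#' @param n_init size of the initial Latin hypercube design; default
#'   `min(2 * (d + 1), budget - 2)`.
#' @param n_cand candidate points scored per iteration.
#' @param polish_frac fraction of the budget reserved for a final
#'   deterministic coordinate-descent refinement of the incumbent.
#'
#' @return A list with `par` (best point), `value` (best objective), `n_eval`,
#'   and the evaluation history (`X`, `y`).
#' @export
rbf_optimize <- function(fn, lower, upper, budget = 100, seed = 1,
                         n_init = NULL, n_cand = 800, polish_frac = 0.3) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  if (budget < d) stop("budget must be at least the problem dimension")
  if (is.null(n_init)) n_init <- min(2L * (d + 1L), budget - 2L)
  n_init <- max(min(n_init, budget), 2L)
  span <- upper - lower
  from_unit <- function(u) lower + u * span
  n_polish <- if (budget > n_init + 10) round(polish_frac * budget) else 0L
  n_rbf <- budget - n_polish

  with_seed(seed, {
    U <- lhs::maximinLHS(n_init, d)
    y <- apply(U, 1, function(u) fn(from_unit(u)))

    # surrogate weight cycle: high = trust the model (exploit),
    # low = favour unexplored regions (explore)
    wcycle <- c(0.95, 0.9, 0.7, 0.95, 0.3)
    it <- 0L
    while (nrow(U) < n_rbf) {
      it <- it + 1L
      w <- wcycle[(it - 1L) %% length(wcycle) + 1L]
      model <- .rbf_fit(U, y)
      best <- U[which.min(y), , drop = FALSE]

      # candidates: local Gaussian perturbations of the incumbent + uniform
      n_loc <- round(0.8 * n_cand)
      sd_loc <- if (w >= 0.9) 0.03 else if (w >= 0.6) 0.1 else 0.25
      C1 <- matrix(rep(best, each = n_loc), nrow = n_loc) +
        matrix(stats::rnorm(n_loc * d, sd = sd_loc), nrow = n_loc)
      C2 <- matrix(stats::runif((n_cand - n_loc) * d), ncol = d)
      C <- rbind(pmin(pmax(C1, 0), 1), C2)

      pred <- .rbf_predict(model, C)
      dmin <- .min_dist(C, U)
      # normalize both criteria to [0,1] before mixing
      pr <- (pred - min(pred)) / max(max(pred) - min(pred), 1e-12)
      dr <- 1 - (dmin - min(dmin)) / max(max(dmin) - min(dmin), 1e-12)
      score <- w * pr + (1 - w) * dr
      score[dmin < 1e-6] <- Inf  # never re-evaluate a known point
      u_new <- C[which.min(score), ]
      if (!is.finite(min(score))) u_new <- stats::runif(d)

      U <- rbind(U, u_new)
      y <- c(y, fn(from_unit(u_new)))
    }

    # deterministic coordinate-descent polish of the incumbent
    if (n_polish > 0) {
      ubest <- U[which.min(y), ]
      ybest <- min(y)
      step <- 0.08
      left <- n_polish
      while (left > 0 && step > 1e-3) {
        improved <- FALSE
        for (j in seq_len(d)) {
          if (left <= 0) break
          for (s in c(-step, step)) {
            if (left <= 0) break
            cand <- ubest
            cand[j] <- min(max(cand[j] + s, 0), 1)
            if (abs(cand[j] - ubest[j]) < 1e-12) next
            yc <- fn(from_unit(cand))
            U <- rbind(U, cand); y <- c(y, yc); left <- left - 1L
            if (yc < ybest) { ubest <- cand; ybest <- yc; improved <- TRUE
              break }
          }
        }
        if (!improved) step <- step / 3
      }
    }

    i <- which.min(y)
    list(par = from_unit(U[i, ]), value = y[i], n_eval = nrow(U),
         X = t(apply(U, 1, from_unit)), y = y)
  })
}

# Cubic RBF interpolant with linear tail: s(x) = sum lambda_i ||x - x_i||^3
# + c0 + c' x.  A small ridge keeps the system solvable with near-duplicate
# or degenerate designs.
.rbf_fit <- function(U, y) {
  n <- nrow(U); d <- ncol(U)
  D <- as.matrix(stats::dist(U))
  Phi <- D^3
  P <- cbind(1, U)
  A <- rbind(cbind(Phi + diag(1e-8, n), P),
             cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- c(y, rep(0, d + 1))
  coef <- tryCatch(solve(A, rhs),
                   error = function(e) qr.solve(A, rhs, tol = 1e-12))
  list(U = U, lambda = coef[seq_len(n)], tail = coef[n + seq_len(d + 1)])
}

.rbf_predict <- function(model, C) {
  cross <- .cross_dist(C, model$U)
  as.numeric(cross^3 %*% model$lambda + cbind(1, C) %*% model$tail)
}

# Euclidean distances between rows of A and rows of B
.cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  M <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(M, 0))
}

.min_dist <- function(C, U) apply(.cross_dist(C, U), 1, min)
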