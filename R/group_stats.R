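# Group statistics: timewise within-subject sign-flip permutation tests,
# two-stage adaptive FDR control, the dependent-samples probability of
# superiority, and trial-count-balancing control draws.

#' Timewise within-subject permutation test
#'
#' Paired comparison of two conditions, one time course per subject and
#' condition. The observed statistic at each time point is the group mean of
#' the paired differences. The null distribution is built by random sign
#' flips of each subject's whole difference trace (the flip pattern is shared
#' across time points within a permutation, preserving the temporal
#' correlation of the null). Two-tailed p-values use the add-one convention
#' `p = (#{|null| >= |obs|} + 1) / (n_perm + 1)` (equivalently, rejections at
#' the 2.5/97.5 percentile tails of the permutation distribution), and the
#' family of time points is corrected with [adaptive_fdr()].
#'
#' The reported effect size `delta_dep` is the dependent-samples probability
#' of superiority computed on subject values averaged over the significant
#' time window (`NA` when nothing survives FDR control).
#'
#' @param cond_a,cond_b numeric matrices subjects x samples (paired rows).
#' @param times optional time axis (seconds) for reporting.
#' @param n_perm number of permutations.
#' @param q FDR level.
#' @param seed optional seed for the flip patterns.
#' @return object of class `timewise_test`: `times`, `observed`, `p`,
#'   `p_star` (largest rejected p, `NA` if none), `significant` (logical
#'   mask), `delta_dep`, `n_perm`, `q`, `n_subjects`.
#' @export
timewise_perm_test <- function(cond_a, cond_b, times = NULL, n_perm = 500,
                               q = 0.05, seed = NULL) {
  if (!is.matrix(cond_a) || !is.matrix(cond_b) ||
      !all(dim(cond_a) == dim(cond_b)))
    stop("conditions must be matrices of identical shape")
  if (anyNA(cond_a) || anyNA(cond_b)) stop("NA values in input")
  n <- nrow(cond_a)
  if (n < 5) stop("need at least 5 subjects for the permutation null")
  if (!is.null(seed)) set.seed(seed)
  d <- cond_a - cond_b
  obs <- colMeans(d)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  null <- flips %*% d / n                       # n_perm x samples
  exceed <- colSums(abs(null) >= matrix(abs(obs), n_perm, length(obs),
                                        byrow = TRUE))
  p <- (exceed + 1) / (n_perm + 1)
  fdr <- adaptive_fdr(p, q)
  dd <- NA_real_
  if (any(fdr$significant)) {
    xa <- rowMeans(cond_a[, fdr$significant, drop = FALSE])
    xb <- rowMeans(cond_b[, fdr$significant, drop = FALSE])
    dd <- delta_dep(xa, xb)
  }
  structure(list(times = if (is.null(times)) seq_along(obs) else times,
                 observed = obs, p = p, p_star = fdr$p_star,
                 significant = fdr$significant, delta_dep = dd,
                 n_perm = n_perm, q = q, n_subjects = n),
            class = "timewise_test")
}

#' @export
print.timewise_test <- function(x, ...) {
  cat(sprintf("timewise_test: %d time points, %d subjects, %d permutations\n",
              length(x$p), x$n_subjects, x$n_perm))
  if (any(x$significant)) {
    rng <- range(x$p[x$significant])
    cat(sprintf("  %d significant points (P_FDR = %.4g-%.4g), delta_dep = %.4g\n",
                sum(x$significant), rng[1], rng[2], x$delta_dep))
  } else cat("  no significant points after FDR control\n")
  invisible(x)
}

# one-stage Benjamini-Hochberg step-up at level `level`; returns logical mask
.bh_stepup <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * level)
  mask <- rep(FALSE, m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

#' Adaptive two-stage linear step-up FDR control
#'
#' Two-stage procedure: a first linear step-up pass at level `q / (1 + q)`
#' estimates the number of true nulls as `m - r1` (with `r1` first-pass
#' rejections); if `0 < r1 < m`, a second step-up is run at the adjusted
#' level `q / (1 + q) * m / (m - r1)`. This adaptivity recovers power when
#' many hypotheses are false while keeping the FDR at `q`.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level.
#' @return list with `significant` (logical mask), `p_star` (largest rejected
#'   p-value, `NA` when nothing is rejected), `n_rejected`.
#' @export
adaptive_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  q1 <- q / (1 + q)
  mask1 <- .bh_stepup(p, q1)
  r1 <- sum(mask1)
  m <- length(p)
  mask <- if (r1 == 0) {
    rep(FALSE, m)
  } else if (r1 == m) {
    rep(TRUE, m)
  } else {
    .bh_stepup(p, q1 * m / (m - r1))
  }
  list(significant = mask,
       p_star = if (any(mask)) max(p[mask]) else NA_real_,
       n_rejected = sum(mask))
}

#' Probability of superiority for dependent samples
#'
#' Nonparametric effect size for paired data: the proportion of pairs in
#' which `x` exceeds `y`, ties counted half:
#' `(#{x_i > y_i} + 0.5 #{x_i = y_i}) / n`. Ranges from 0 to 1, with 0.5
#' meaning no systematic difference.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return the effect size in [0, 1].
#' @export
delta_dep <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  (sum(x > y) + 0.5 * sum(x == y)) / n
}

#' Trial-count-balancing control draws
#'
#' Draws `n_runs` index multisets of size `n_target` with replacement from a
#' trial pool. Used to re-run contrasts with the (larger) diastole-cued or
#' all-trials pools subsampled to each subject's systole-cued trial count, so
#' that significant effects cannot be attributed to unequal trial numbers.
#'
#' @param pool vector of trial indices to draw from.
#' @param n_target size of each draw (typically the systole trial count).
#' @param n_runs number of control runs.
#' @param seed optional seed.
#' @return list of `n_runs` integer vectors, each of length `n_target`.
#' @export
balanced_control_runs <- function(pool, n_target, n_runs = 10, seed = NULL) {
  if (length(pool) == 0) stop("empty trial pool")
  if (n_target < 1) stop("'n_target' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  # index into the pool explicitly: sample(x) on a length-1 numeric pool
  # would otherwise sample from 1:x
  lapply(seq_len(n_runs), function(i)
    pool[sample.int(length(pool), n_target, replace = TRUE)])
}
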