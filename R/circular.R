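# Circular statistics of cue angles: trial-wise suppression index,
# percentile-thresholded trial selection, subject- and group-level Rayleigh
# tests, a Monte-Carlo null for the group statistic, and the systole-overlap
# summary.

#' Trial-wise contralateral suppression index
#'
#' For each trial, the ipsilateral minus contralateral baseline-z-scored band
#' power of a region, averaged over a fixed post-cue window (normally the
#' significant window of the all-trials ipsi-vs-contra contrast). Positive
#' values mean the contralateral trace is more negative (more suppressed)
#' than the ipsilateral one.
#'
#' @param bps a [band_average()] result with per-trial `side` metadata.
#' @param region region name (`"M1"` or `"S1"` with the default channels).
#' @param band band name.
#' @param window averaging window (start, end) in s relative to the cue.
#' @return numeric vector, one index per trial, with attributes `region`,
#'   `band`, `window`.
#' @export
suppression_index <- function(bps, region, band, window) {
  if (length(window) != 2 || diff(window) <= 0)
    stop("empty suppression window: supply a fallback window")
  lat <- laterality_traces(bps, region, band)
  sel <- lat$t >= window[1] & lat$t < window[2]
  if (!any(sel)) stop("suppression window lies outside the epoch")
  idx <- rowMeans(lat$ipsi[, sel, drop = FALSE]) -
    rowMeans(lat$contra[, sel, drop = FALSE])
  attr(idx, "region") <- region
  attr(idx, "band") <- band
  attr(idx, "window") <- window
  idx
}

#' Select trials with pronounced contralateral suppression
#'
#' Returns the trials whose suppression index lies strictly above the given
#' percentile of the subject's own index distribution. Selections are nested:
#' the 90th-percentile set is contained in the 75th, which is contained in
#' the 50th.
#'
#' @param index suppression index vector (>= 10 trials).
#' @param percentile threshold percentile (e.g. 50, 75, 90).
#' @return integer vector of selected trial indices.
#' @export
select_trials <- function(index, percentile) {
  if (length(index) < 10) stop("need at least 10 trials")
  thr <- quantile(index, percentile / 100, names = FALSE, na.rm = TRUE)
  which(index > thr)
}

#' Rayleigh p-value from the sample size and mean resultant length
#'
#' Small-sample approximation to the p-value of the Rayleigh test of circular
#' uniformity: with `R = n * rbar`,
#' `P = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, clamped to (0, 1].
#'
#' @param n number of angles.
#' @param rbar mean resultant length in [0, 1].
#' @return the approximate p-value.
#' @export
rayleigh_p <- function(n, rbar) {
  stopifnot(n >= 1, rbar >= 0, rbar <= 1 + 1e-12)
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(p, 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles concentrate around a common direction. Reports the
#' mean resultant length `rbar = |mean(exp(i*theta))|`, the statistic
#' `Z = n * rbar^2`, the approximate p-value (see [rayleigh_p()]) and the
#' mean direction. `rbar`, `Z` and `p` are all reported explicitly because
#' published work sometimes prints `rbar` under the name "Z".
#'
#' @param angles angles in radians (n >= 3, finite).
#' @return object of class `rayleigh_test`: `n`, `rbar`, `Z`, `p`,
#'   `mean_direction` (radians in [0, 2*pi)).
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 3) stop("need at least 3 finite angles")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  rbar <- sqrt(C^2 + S^2)
  structure(list(n = n, rbar = rbar, Z = n * rbar^2,
                 p = rayleigh_p(n, rbar),
                 mean_direction = atan2(S, C) %% (2 * pi)),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, rbar = %.4f, Z = %.4f, p = %.4g, mean direction = %.3f rad\n",
              x$n, x$rbar, x$Z, x$p, x$mean_direction))
  invisible(x)
}

#' Group-level (second-order) Rayleigh test
#'
#' Subject-level Rayleigh tests are computed on each subject's angles; the
#' subject mean directions are then treated as unit vectors and submitted to
#' a group-level Rayleigh test. This second-order test discards subject-level
#' concentration (a subject with rbar 0.1 counts like one with rbar 0.9); a
#' weighted mode using the subject resultant lengths as vector lengths is
#' available. Subjects with fewer than 3 usable angles are dropped with a
#' message.
#'
#' @param subject_angles list of numeric vectors, one per subject (radians).
#' @param weights `"unit"` (default) or `"rbar"`.
#' @return list of class `group_rayleigh`: `subjects` (data.frame with n,
#'   mean_direction, rbar, Z, p per retained subject), `group` (a
#'   `rayleigh_test`-like list), `n_subjects`, `weights`.
#' @export
group_rayleigh <- function(subject_angles, weights = c("unit", "rbar")) {
  weights <- match.arg(weights)
  stopifnot(is.list(subject_angles))
  usable <- vapply(subject_angles,
                   function(a) sum(is.finite(a)) >= 3, logical(1))
  if (any(!usable))
    message(sum(!usable), " subject(s) dropped: fewer than 3 usable angles")
  if (sum(usable) < 3) stop("need at least 3 subjects with defined directions")
  subj <- lapply(subject_angles[usable], rayleigh_test)
  df <- data.frame(n = vapply(subj, `[[`, 1, "n"),
                   mean_direction = vapply(subj, `[[`, 1, "mean_direction"),
                   rbar = vapply(subj, `[[`, 1, "rbar"),
                   Z = vapply(subj, `[[`, 1, "Z"),
                   p = vapply(subj, `[[`, 1, "p"))
  ns <- nrow(df)
  if (weights == "unit") {
    grp <- rayleigh_test(df$mean_direction)
  } else {
    C <- mean(df$rbar * cos(df$mean_direction))
    S <- mean(df$rbar * sin(df$mean_direction))
    rbar <- sqrt(C^2 + S^2)
    grp <- list(n = ns, rbar = rbar, Z = ns * rbar^2,
                p = rayleigh_p(ns, rbar),
                mean_direction = atan2(S, C) %% (2 * pi))
    class(grp) <- "rayleigh_test"
  }
  structure(list(subjects = df, group = grp, n_subjects = ns,
                 weights = weights),
            class = "group_rayleigh")
}

#' @export
print.group_rayleigh <- function(x, ...) {
  cat(sprintf("group_rayleigh (%s vectors): %d subjects\n", x$weights,
              x$n_subjects))
  print(x$group)
  invisible(x)
}

#' Monte-Carlo null distribution of the group Rayleigh statistic
#'
#' For each permutation, angles are drawn uniformly on [0, 2*pi) for every
#' trial of every subject; subject mean directions are computed and the
#' group-level Rayleigh statistic `Z = n_subjects * rbar^2` of those
#' directions recorded. The empirical p-value of an observed statistic uses
#' the add-one convention (see [empirical_p()]).
#'
#' @param trial_counts integer vector: number of selected trials per subject.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed optional seed.
#' @return numeric vector of `n_perm` null group Z values.
#' @export
monte_carlo_null <- function(trial_counts, n_perm = 1000, seed = NULL) {
  stopifnot(all(trial_counts >= 1), length(trial_counts) >= 3)
  if (!is.null(seed)) set.seed(seed)
  total <- sum(trial_counts)
  grp <- rep(seq_along(trial_counts), trial_counts)
  ns <- length(trial_counts)
  # draw all permutations at once, chunked to bound memory
  chunk <- max(1L, floor(2e7 / total))
  out <- numeric(0)
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    th <- matrix(runif(total * k, 0, 2 * pi), total, k)
    C <- rowsum(cos(th), grp)
    S <- rowsum(sin(th), grp)
    mu <- atan2(S, C)                        # subjects x k mean directions
    rbar <- sqrt(colMeans(cos(mu))^2 + colMeans(sin(mu))^2)
    out <- c(out, ns * rbar^2)
    done <- done + k
  }
  out
}

#' Empirical p-value with the add-one convention
#'
#' @param observed observed statistic.
#' @param null vector of null statistics.
#' @return `(#{null >= observed} + 1) / (length(null) + 1)`.
#' @export
empirical_p <- function(observed, null) {
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Overlap between a significant window and the next systolic interval
#'
#' For each diastole-cued trial, computes the length of the temporal
#' intersection between the (cue-relative) significant window and the next
#' systolic interval after the cue, i.e. from the next R peak to that beat's
#' T-wave offset, expressed relative to the cue. Cues lacking a subsequent
#' complete beat are skipped.
#'
#' @param sig_window significant window (start, end) in s relative to the cue.
#' @param events a `cardiac_events` object (or ground-truth equivalent).
#' @param cue_times onsets of the diastole-cued trials, s.
#' @return list with `per_cue` overlaps (s, one per usable cue) and their
#'   `mean`.
#' @export
systole_overlap_summary <- function(sig_window, events, cue_times) {
  stopifnot(length(sig_window) == 2, diff(sig_window) >= 0)
  r <- events$r_times
  t_off <- events$t_offsets
  per_cue <- numeric(0)
  for (ci in cue_times) {
    k <- findInterval(ci, r)
    nk <- k + 1L                               # next beat after the cue
    if (nk < 1L || nk > length(t_off) || is.na(t_off[nk])) next
    sys_rel <- c(r[nk] - ci, t_off[nk] - ci)
    ov <- max(0, min(sig_window[2], sys_rel[2]) -
                 max(sig_window[1], sys_rel[1]))
    per_cue <- c(per_cue, ov)
  }
  list(per_cue = per_cue,
       mean = if (length(per_cue)) mean(per_cue) else NA_real_)
}
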