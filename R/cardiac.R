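# Cardiac event chain: ECG conditioning, R-peak and T-wave offset
# delineation, cue phase labelling and cycle-angle computation, and
# regression-based removal of the cardiac-field artifact.

#' Band-pass filter an ECG trace
#'
#' Zero-phase FIR band-pass between 0.2 and 40 Hz, removing slow drifts and
#' attenuating muscle artifacts while preserving QRS and T-wave morphology.
#'
#' @param ecg numeric ECG trace.
#' @param fs sampling rate in Hz; must exceed 80 Hz so the 40 Hz edge lies
#'   inside the representable band.
#' @param low,high band edges in Hz.
#' @return filtered trace, same length as the input.
#' @export
preprocess_ecg <- function(ecg, fs, low = 0.2, high = 40) {
  if (anyNA(ecg)) stop("ECG contains NA values")
  if (fs <= 80) stop("sampling rate too low for the 40 Hz band edge")
  fir_filter(ecg, fs, low = low, high = high, transition = low)
}

#' Detect R peaks in a preprocessed ECG
#'
#' Amplitude-threshold peak picking with automatic polarity correction and a
#' 250 ms refractory period. Designed for traces already conditioned by
#' [preprocess_ecg()].
#'
#' @param ecg filtered ECG trace.
#' @param fs sampling rate, Hz.
#' @param refractory minimum inter-peak distance, s.
#' @return sorted R-peak times in seconds (time of sample i is `(i-1)/fs`).
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25) {
  if (anyNA(ecg)) stop("ECG contains NA values")
  n <- length(ecg)
  if (n < 3) stop("signal too short")
  # polarity: R deflection should dominate the positive tail
  q_hi <- quantile(ecg, 0.999, names = FALSE)
  q_lo <- quantile(ecg, 0.001, names = FALSE)
  med <- median(ecg)
  if (abs(q_lo - med) > abs(q_hi - med)) {
    ecg <- -ecg
    q_hi <- quantile(ecg, 0.999, names = FALSE)
  }
  thr <- med + 0.5 * (q_hi - med)
  core <- ecg[2:(n - 1)]
  cand <- which(core > ecg[1:(n - 2)] & core >= ecg[3:n] & core >= thr) + 1L
  if (length(cand) == 0) stop("fewer than 5 beats found")
  # enforce refractory period, keeping the larger peak on conflict
  ord <- cand[order(ecg[cand], decreasing = TRUE)]
  min_gap <- refractory * fs
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 || all(abs(keep - i) >= min_gap))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 5) stop("fewer than 5 beats found")
  (keep - 1) / fs
}

#' Detect T-wave offsets by the tangent method
#'
#' For every beat with a successor, the T peak is located inside the search
#' window (R + 150 ms, R + 0.6 IBI); the offset is the baseline crossing of
#' the tangent through the steepest point of the descending T limb. Beats
#' where no credible T wave is found are flagged `NA` rather than fabricated.
#'
#' @param ecg filtered ECG trace (zero baseline assumed, as after
#'   [preprocess_ecg()]).
#' @param r_times sorted R-peak times, s (at least 2).
#' @param fs sampling rate, Hz.
#' @return numeric vector of T-wave offset times, one per complete beat
#'   (`length(r_times) - 1`), `NA` where delineation failed.
#' @export
detect_t_offsets <- function(ecg, r_times, fs) {
  if (length(r_times) < 2) stop("need at least 2 R peaks")
  nb <- length(r_times)
  out <- rep(NA_real_, nb - 1)
  for (k in seq_len(nb - 1)) {
    ibi <- r_times[k + 1] - r_times[k]
    i0 <- floor((r_times[k] + 0.15) * fs) + 1L
    i1 <- ceiling((r_times[k] + 0.6 * ibi) * fs) + 1L
    i1 <- min(i1, length(ecg))
    if (i1 - i0 < 4) next
    seg <- ecg[i0:i1]
    tp <- which.max(seg)
    r_amp <- ecg[round(r_times[k] * fs) + 1L]
    if (!is.finite(r_amp) || seg[tp] < 0.08 * abs(r_amp)) next  # no T bump
    if (tp >= length(seg) - 1) next
    d <- diff(seg[tp:length(seg)]) * fs       # slope per second
    j <- which.min(d)
    slope <- d[j]
    if (slope >= 0) next
    # local baseline: quiet late-diastolic level between the end of the T
    # search window and the next P wave (robust to the small drift the
    # 0.2 Hz high-pass introduces around each beat)
    b0 <- floor((r_times[k] + 0.6 * ibi + 0.03) * fs) + 1L
    b1 <- min(ceiling((r_times[k + 1] - 0.22) * fs) + 1L, length(ecg))
    if (b1 <= b0) b1 <- min(b0 + max(2L, round(0.03 * fs)), length(ecg))
    base <- if (b1 > b0) median(ecg[b0:b1]) else 0
    # tangent through the inter-sample midpoint of the steepest descent
    y_mid <- (seg[tp + j - 1] + seg[tp + j]) / 2
    t_mid <- (i0 - 1 + tp + j - 1.5) / fs
    t_off <- t_mid + (y_mid - base) / (-slope)
    if (t_off > (i0 - 1 + tp - 1) / fs && t_off < r_times[k + 1])
      out[k] <- t_off
  }
  out
}

#' Delineate all cardiac events from a filtered ECG
#'
#' Convenience wrapper returning the temporal skeleton used for phase
#' labelling: R times, T-wave offsets and inter-beat intervals.
#'
#' @param ecg filtered ECG trace.
#' @param fs sampling rate, Hz.
#' @return list of class `cardiac_events` with `r_times`, `t_offsets` (one per
#'   complete beat, `NA` where missing) and `ibis`.
#' @export
cardiac_events <- function(ecg, fs) {
  r <- detect_r_peaks(ecg, fs)
  t_off <- detect_t_offsets(ecg, r, fs)
  structure(list(r_times = r, t_offsets = t_off, ibis = diff(r)),
            class = "cardiac_events")
}

#' @export
print.cardiac_events <- function(x, ...) {
  cat(sprintf("cardiac_events: %d beats, mean IBI %.3f s, %d missing T offsets\n",
              length(x$r_times), mean(x$ibis), sum(is.na(x$t_offsets))))
  invisible(x)
}

#' Label each cue systole or diastole
#'
#' Ventricular systole is the half-open interval from the R peak to the
#' T-wave offset of the same beat; diastole runs from the T-wave offset to the
#' next R peak. A cue exactly at the R peak is systolic; exactly at the T-wave
#' offset, diastolic. Cues outside covered beats, or inside beats whose T-wave
#' offset could not be delineated, are returned as `NA`.
#'
#' @param cue_times cue onsets, s.
#' @param events a `cardiac_events` object, or any list with `r_times` and
#'   `t_offsets`.
#' @return character vector `"systole"` / `"diastole"` / `NA` per cue.
#' @export
label_cue_phase <- function(cue_times, events) {
  r <- events$r_times
  t_off <- events$t_offsets
  k <- findInterval(cue_times, r)
  out <- rep(NA_character_, length(cue_times))
  ok <- k >= 1 & k < length(r) & !is.na(t_off[pmax(k, 1)])
  kk <- k[ok]
  out[ok] <- ifelse(cue_times[ok] < t_off[kk], "systole", "diastole")
  out
}

#' Cue angle on the cardiac cycle
#'
#' The latency from the preceding R peak to the cue is converted to an angle
#' `theta = 2*pi * (C - R) / IBI` wrapped to `[0, 2*pi)`, where IBI is the
#' mean of up to four R-R intervals immediately preceding that R peak (a
#' robustness device against single noisy beats; fewer than four are averaged
#' over however many exist). Cues before the second R peak have no preceding
#' interval and are flagged `NA`.
#'
#' @param cue_times cue onsets, s.
#' @param events a `cardiac_events` object or list with `r_times`.
#' @return data.frame with one row per cue: `cue_time`, `r_time` (preceding R),
#'   `ibi_used_s`, `theta_rad`.
#' @export
cue_angle <- function(cue_times, events) {
  r <- events$r_times
  ibis <- diff(r)
  k <- findInterval(cue_times, r)
  n <- length(cue_times)
  out <- data.frame(cue_time = cue_times, r_time = NA_real_,
                    ibi_used_s = NA_real_, theta_rad = NA_real_)
  for (i in seq_len(n)) {
    if (k[i] < 2) next                      # no preceding R-R interval
    prev <- ibis[max(1L, k[i] - 4L):(k[i] - 1L)]
    prev <- tail(prev, 4L)
    ibi_i <- mean(prev)
    out$r_time[i] <- r[k[i]]
    out$ibi_used_s[i] <- ibi_i
    out$theta_rad[i] <- (2 * pi * (cue_times[i] - r[k[i]]) / ibi_i) %% (2 * pi)
  }
  out
}

#' Enrich a cue table with cardiac phase and angle
#'
#' @param cues data.frame with column `onset_s` (plus any metadata).
#' @param events a `cardiac_events` object.
#' @return the cue table with added columns `phase`, `theta_rad`,
#'   `ibi_used_s`.
#' @export
annotate_cues <- function(cues, events) {
  stopifnot(is.data.frame(cues), "onset_s" %in% names(cues))
  ang <- cue_angle(cues$onset_s, events)
  cues$phase <- label_cue_phase(cues$onset_s, events)
  cues$theta_rad <- ang$theta_rad
  cues$ibi_used_s <- ang$ibi_used_s
  cues
}

#' Remove the cardiac-field artifact by regression on the ECG
#'
#' Per neural channel, an ordinary-least-squares fit of the neural trace on
#' the concurrent ECG trace (plus intercept) is computed across all epoch
#' samples pooled (stabler slope than per-epoch fits; a per-epoch mode is
#' available), and the fitted component is subtracted.
#'
#' @param neural numeric array trials x channels x samples.
#' @param ecg numeric matrix trials x samples, time-aligned with `neural`.
#' @param per_epoch if `TRUE`, fit a separate slope per epoch.
#' @return cleaned array with the shape of `neural`.
#' @export
regress_cardiac_artifact <- function(neural, ecg, per_epoch = FALSE) {
  stopifnot(length(dim(neural)) == 3, is.matrix(ecg))
  if (dim(neural)[1] != nrow(ecg) || dim(neural)[3] != ncol(ecg))
    stop("neural and ECG epochs are not time-aligned")
  out <- neural
  ols_clean <- function(y, x) {
    vx <- var(x)
    if (!is.finite(vx) || vx == 0) stop("zero-variance ECG regressor")
    b <- cov(y, x) / vx
    # subtract only the ECG-aligned component; the intercept keeps the
    # neural mean untouched
    y - b * (x - mean(x))
  }
  for (ch in seq_len(dim(neural)[2])) {
    if (per_epoch) {
      for (tr in seq_len(dim(neural)[1]))
        out[tr, ch, ] <- ols_clean(neural[tr, ch, ], ecg[tr, ])
    } else {
      y <- as.vector(t(neural[, ch, , drop = TRUE]))
      if (dim(neural)[1] == 1) y <- as.vector(neural[1, ch, ])
      x <- as.vector(t(ecg))
      cleaned <- ols_clean(y, x)
      out[, ch, ] <- matrix(cleaned, nrow = dim(neural)[1], byrow = TRUE)
    }
  }
  out
}
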