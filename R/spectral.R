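# Spectral chain: epoching, Morlet time-frequency power, baseline z-scoring,
# and band averaging to alpha/beta time courses.

#' Epoch a recording around cue onsets
#'
#' Extracts one trial per usable cue over the half-open window
#' `[window[1], window[2])` relative to cue onset (default -1 to 4 s). Cues
#' whose window is not fully covered by the recording are dropped with a
#' message.
#'
#' @param recording a [physio_recording()].
#' @param cues data.frame with `onset_s` and any per-trial metadata
#'   (`side`, `task`, `phase`, `theta_rad`, ...), carried along.
#' @param window epoch window (start, end) relative to the cue, s.
#' @param channels channel names to extract (default: all).
#' @return object of class `epoch_set`: `data` (trials x channels x samples),
#'   `t` (sample times relative to the cue), `fs`, `channels`, `info`
#'   (metadata of the retained cues).
#' @export
epoch_recording <- function(recording, cues, window = c(-1, 4),
                            channels = NULL) {
  stopifnot(inherits(recording, "physio_recording"),
            is.data.frame(cues), "onset_s" %in% names(cues))
  if (is.null(channels)) channels <- recording$channels
  missing_ch <- setdiff(channels, recording$channels)
  if (length(missing_ch))
    stop("unknown channels: ", paste(missing_ch, collapse = ", "))
  fs <- recording$fs
  n_win <- round(diff(window) * fs)
  start_idx <- round((cues$onset_s + window[1]) * fs) + 1L
  keep <- start_idx >= 1L & (start_idx + n_win - 1L) <= nrow(recording$data)
  if (!any(keep))
    stop("no cue has full window coverage: misaligned events?")
  if (any(!keep))
    message(sum(!keep), " cue(s) dropped: incomplete epoch window")
  idx <- which(keep)
  data <- array(NA_real_, c(length(idx), length(channels), n_win),
                dimnames = list(NULL, channels, NULL))
  cols <- match(channels, recording$channels)
  for (i in seq_along(idx)) {
    rows <- start_idx[idx[i]]:(start_idx[idx[i]] + n_win - 1L)
    data[i, , ] <- t(recording$data[rows, cols, drop = FALSE])
  }
  structure(list(data = data,
                 t = window[1] + (seq_len(n_win) - 1) / fs,
                 fs = fs, channels = channels,
                 info = cues[idx, , drop = FALSE]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples (%.2f..%.2f s, %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$t), max(x$t) + 1 / x$fs, x$fs))
  invisible(x)
}

# complex Morlet wavelet at frequency f, n_cycles cycles, L2-normalized
.morlet_wavelet <- function(f, fs, n_cycles) {
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(5 * sigma * fs)
  tw <- (-half:half) / fs
  w <- exp(-tw^2 / (2 * sigma^2)) * exp(2i * pi * f * tw)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet time-frequency power
#'
#' Squared magnitude of the convolution of each epoch with complex Morlet
#' wavelets (default 5 cycles, one bin per integer frequency from 8 to
#' 30 Hz), computed by FFT convolution over the full epoch.
#'
#' @param epochs an [epoch_recording()] result.
#' @param freqs frequencies of interest, Hz.
#' @param n_cycles wavelet cycles (constant across frequencies).
#' @return object of class `tfr_set`: `power` (trials x channels x freqs x
#'   samples), `t`, `freqs`, `fs`, `channels`, `info`.
#' @export
morlet_power <- function(epochs, freqs = 8:30, n_cycles = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (max(freqs) >= fs / 2)
    stop("requested frequency at or above the Nyquist frequency")
  n_samp <- dim(epochs$data)[3]
  min_len <- n_cycles / min(freqs)
  if (n_samp / fs < min_len)
    stop(sprintf("epoch too short: %.3f s needed for %g cycles at %g Hz",
                 min_len, n_cycles, min(freqs)))
  wl <- lapply(freqs, .morlet_wavelet, fs = fs, n_cycles = n_cycles)
  max_half <- max(vapply(wl, function(w) (length(w) - 1L) %/% 2L, integer(1)))
  nfft <- stats::nextn(n_samp + 2L * max_half + 1L, 2)
  # kernel FFTs with the wavelet centered on index 1 (circular convolution)
  wf <- vapply(wl, function(w) {
    half <- (length(w) - 1L) / 2L
    kv <- complex(nfft)
    kv[1:(half + 1L)] <- w[(half + 1L):length(w)]
    kv[(nfft - half + 1L):nfft] <- w[1:half]
    fft(kv)
  }, complex(nfft))

  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  power <- array(NA_real_, c(n_tr, n_ch, length(freqs), n_samp),
                 dimnames = list(NULL, epochs$channels, as.character(freqs),
                                 NULL))
  pad <- numeric(nfft)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      pad[1:n_samp] <- epochs$data[tr, ch, ]
      pad[(n_samp + 1L):nfft] <- 0
      xf <- fft(pad)
      for (fi in seq_along(freqs)) {
        conv <- fft(xf * wf[, fi], inverse = TRUE) / nfft
        power[tr, ch, fi, ] <- Mod(conv[1:n_samp])^2
      }
    }
  }
  structure(list(power = power, t = epochs$t, freqs = freqs, fs = fs,
                 channels = epochs$channels, info = epochs$info),
            class = "tfr_set")
}

#' Baseline z-score of time-frequency power
#'
#' Normalizes each power time course to its pre-cue baseline:
#' `z(t) = (P(t) - mean_baseline) / sd_baseline`. By default the baseline
#' mean and SD are computed per trial, channel and frequency over the
#' baseline samples of that same trial; a trial-pooled mode (statistics
#' shared across trials of a channel/frequency) is available.
#'
#' @param tfr a [morlet_power()] result.
#' @param baseline baseline window (start, end) relative to the cue, s;
#'   half-open.
#' @param mode `"trial"` (per-trial statistics, default) or `"pooled"`.
#' @return `tfr_set` whose `power` holds z-scored values (units: SD). Trials
#'   with a zero baseline SD at any frequency are flagged in
#'   `attr(, "flagged_trials")` and set to `NA`.
#' @export
baseline_zscore <- function(tfr, baseline = c(-0.5, 0),
                            mode = c("trial", "pooled")) {
  stopifnot(inherits(tfr, "tfr_set"))
  mode <- match.arg(mode)
  bsel <- tfr$t >= baseline[1] & tfr$t < baseline[2]
  if (!any(bsel)) stop("baseline window lies outside the epoch")
  z <- tfr$power
  flagged <- integer(0)
  n_tr <- dim(z)[1]; n_ch <- dim(z)[2]
  if (mode == "trial") {
    for (tr in seq_len(n_tr)) {
      for (ch in seq_len(n_ch)) {
        p <- z[tr, ch, , , drop = TRUE]
        if (is.null(dim(p))) p <- matrix(p, nrow = 1)
        m <- rowMeans(p[, bsel, drop = FALSE])
        s <- apply(p[, bsel, drop = FALSE], 1, sd)
        if (any(s == 0)) { flagged <- c(flagged, tr); s[s == 0] <- NA }
        z[tr, ch, , ] <- (p - m) / s
      }
    }
  } else {
    for (ch in seq_len(n_ch)) {
      for (fi in seq_len(dim(z)[3])) {
        bl <- as.vector(tfr$power[, ch, fi, bsel])
        m <- mean(bl); s <- sd(bl)
        if (s == 0) { flagged <- c(flagged, seq_len(n_tr)); s <- NA }
        z[, ch, fi, ] <- (tfr$power[, ch, fi, ] - m) / s
      }
    }
  }
  out <- tfr
  out$power <- z
  attr(out, "flagged_trials") <- sort(unique(flagged))
  attr(out, "baseline") <- baseline
  out
}

#' Average z-scored power into frequency bands
#'
#' Unweighted mean over the integer frequency bins inside each band (both
#' edges inclusive): with 1 Hz bins, 6 bins for alpha 8--13 Hz and 17 bins
#' for beta 14--30 Hz.
#'
#' @param tfr a (typically z-scored) `tfr_set`.
#' @param bands named list of `(low, high)` band edges in Hz.
#' @return object of class `band_power_set`: `z` (trials x channels x bands x
#'   samples), `t`, `bands`, `fs`, `channels`, `info`.
#' @export
band_average <- function(tfr, bands = list(alpha = c(8, 13),
                                           beta = c(14, 30))) {
  stopifnot(inherits(tfr, "tfr_set"), length(bands) >= 1)
  dims <- dim(tfr$power)
  out <- array(NA_real_, c(dims[1], dims[2], length(bands), dims[4]),
               dimnames = list(NULL, tfr$channels, names(bands), NULL))
  for (b in seq_along(bands)) {
    sel <- tfr$freqs >= bands[[b]][1] & tfr$freqs <= bands[[b]][2]
    if (!any(sel)) stop("no frequency bins inside band '", names(bands)[b], "'")
    for (tr in seq_len(dims[1]))
      for (ch in seq_len(dims[2])) {
        m <- tfr$power[tr, ch, sel, ]
        out[tr, ch, b, ] <- if (is.matrix(m)) colMeans(m) else m
      }
  }
  structure(list(z = out, t = tfr$t, bands = bands, fs = tfr$fs,
                 channels = tfr$channels, info = tfr$info),
            class = "band_power_set")
}

#' @export
print.band_power_set <- function(x, ...) {
  cat(sprintf("band_power_set: %d trials x %d channels x %d bands x %d samples\n",
              dim(x$z)[1], dim(x$z)[2], dim(x$z)[3], dim(x$z)[4]))
  invisible(x)
}

#' Ipsilateral and contralateral band-power traces for a region
#'
#' Maps the two hemispheric channels of a region to ipsilateral/contralateral
#' roles given each trial's cue side (ipsilateral = same hemisphere side as
#' the cued hand).
#'
#' @param bps a [band_average()] result whose channels follow the
#'   `"<region>-lh"` / `"<region>-rh"` naming and whose `info` has `side`.
#' @param region region name, e.g. `"M1"`.
#' @param band band name present in `bps$bands`.
#' @return list with matrices `ipsi` and `contra` (trials x samples) and `t`.
#' @export
laterality_traces <- function(bps, region, band) {
  stopifnot(inherits(bps, "band_power_set"), "side" %in% names(bps$info))
  b <- match(band, names(bps$bands))
  if (is.na(b)) stop("unknown band: ", band)
  lh <- match(paste0(region, "-lh"), bps$channels)
  rh <- match(paste0(region, "-rh"), bps$channels)
  if (is.na(lh) || is.na(rh)) stop("region channels not found: ", region)
  sides <- bps$info$side
  n_tr <- dim(bps$z)[1]
  ipsi <- matrix(NA_real_, n_tr, dim(bps$z)[4])
  contra <- ipsi
  for (tr in seq_len(n_tr)) {
    ih <- if (sides[tr] == "left") lh else rh
    ch <- if (sides[tr] == "left") rh else lh
    ipsi[tr, ] <- bps$z[tr, ih, b, ]
    contra[tr, ] <- bps$z[tr, ch, b, ]
  }
  list(ipsi = ipsi, contra = contra, t = bps$t)
}
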