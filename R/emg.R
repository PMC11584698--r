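# EMG chain: envelope extraction and ipsilateral/contralateral trial
# assignment for phase-split comparisons.

#' EMG envelope: high-pass, full-wave rectification, moving RMS
#'
#' The raw EMG is high-pass filtered at 10 Hz (zero-phase FIR; suppresses
#' motion artifact and drift while keeping the EMG band), full-wave rectified,
#' and smoothed with a centered moving-RMS window (default 100 ms) to retain
#' the mean power of the signal.
#'
#' @param emg numeric EMG trace.
#' @param fs sampling rate, Hz.
#' @param highpass high-pass cutoff, Hz.
#' @param rms_window RMS smoothing window length, s.
#' @return non-negative envelope, same length as the input.
#' @export
preprocess_emg <- function(emg, fs, highpass = 10, rms_window = 0.1) {
  if (anyNA(emg)) stop("EMG contains NA values")
  filtered <- fir_filter(emg, fs, low = highpass, transition = highpass / 2)
  .moving_rms(abs(filtered), round(rms_window * fs))
}

#' Split EMG envelope epochs into ipsilateral and contralateral traces
#'
#' Maps the left/right EMG channels to the hand ipsilateral (same side as the
#' cue) and contralateral (opposite side) per trial. Swapping all cue labels
#' swaps the two roles exactly.
#'
#' @param emg_epochs an [epoch_recording()] result containing both channels
#'   `"EMG-left"` and `"EMG-right"` (typically of envelope recordings).
#' @param sides optional character vector of cue sides per trial; defaults to
#'   `emg_epochs$info$side`.
#' @return list with matrices `ipsi` and `contra` (trials x samples), `t`,
#'   and the per-trial metadata `info`.
#' @export
split_ipsi_contra <- function(emg_epochs, sides = NULL) {
  stopifnot(inherits(emg_epochs, "epoch_set"))
  if (is.null(sides)) sides <- emg_epochs$info$side
  li <- match("EMG-left", emg_epochs$channels)
  ri <- match("EMG-right", emg_epochs$channels)
  if (is.na(li) || is.na(ri)) stop("both EMG channels must be present")
  if (length(sides) != dim(emg_epochs$data)[1])
    stop("one cue side per trial is required")
  n_tr <- dim(emg_epochs$data)[1]
  ipsi <- matrix(NA_real_, n_tr, dim(emg_epochs$data)[3])
  contra <- ipsi
  for (tr in seq_len(n_tr)) {
    ii <- if (sides[tr] == "left") li else ri
    ci <- if (sides[tr] == "left") ri else li
    ipsi[tr, ] <- emg_epochs$data[tr, ii, ]
    contra[tr, ] <- emg_epochs$data[tr, ci, ]
  }
  list(ipsi = ipsi, contra = contra, t = emg_epochs$t,
       info = emg_epochs$info)
}
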