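# Synthetic coupled ECG / neural / EMG session generator.
#
# Every downstream stage of the pipeline is validated against sessions built
# here, because the generator knows the ground truth: exact R-peak and T-wave
# offset times, the cardiac phase and cycle angle of every cue, the programmed
# desynchronization depth of every trial, and the cardiac-field leakage gain.

NEURAL_CHANNELS <- c("M1-lh", "M1-rh", "S1-lh", "S1-rh")
EMG_CHANNELS <- c("EMG-left", "EMG-right")
ALL_CHANNELS <- c(NEURAL_CHANNELS, "ECG", EMG_CHANNELS)

#' Configuration of a synthetic recording session
#'
#' Bundles all generator parameters with validation. Defaults emulate the
#' motor-imagery study conditions: ~8 s trials, 100 left + 100 right cues,
#' inter-beat intervals around 0.9 s, ventricular systole occupying ~35% of
#' each beat (mean systolic duration 0.315 s, inside the 243--546 ms range
#' typical of resting adults), deeper contralateral alpha/beta suppression for
#' diastole-timed cues, ipsilateral-dominant EMG bursts that are larger for
#' diastole-timed cues, pink background noise and an additive cardiac-field
#' artifact proportional to the ECG.
#'
#' @param sampling_rate sampling rate, Hz.
#' @param n_trials_left,n_trials_right number of left / right cues.
#' @param trial_period trial spacing, s.
#' @param ibi_mean,ibi_sd mean and SD of the inter-beat interval, s.
#' @param systole_fraction fraction of each beat occupied by ventricular
#'   systole (the T-wave offset is placed at this fraction of the beat).
#' @param alpha_freq,beta_freq oscillator frequencies, Hz.
#' @param erd_depth_contra_diastole,erd_depth_contra_systole,erd_depth_ipsi
#'   fractional amplitude reduction (0..1) of the alpha/beta oscillators in
#'   the post-cue window, for the contralateral hemisphere split by cue phase
#'   and for the ipsilateral hemisphere.
#' @param erd_window post-cue window (start, end) in s over which the
#'   suppression is applied.
#' @param emg_burst_gain_ipsi,emg_burst_gain_contra EMG burst amplitudes for
#'   the hand ipsilateral / contralateral to the cue.
#' @param emg_phase_gain_diastole multiplier applied to the EMG burst when the
#'   cue falls in diastole.
#' @param artifact_gain ECG-to-neural leakage coefficient.
#' @param noise_sd SD of the pink background noise on neural channels.
#' @param task task label attached to the cues, "MI" or "ME".
#' @param lead_in quiet recording time before the first and after the last
#'   trial, s.
#' @param session_duration total duration, s; defaults to
#'   `2 * lead_in + n_trials * trial_period`.
#' @param seed integer seed; the master seed is fanned out into independent
#'   substreams (heartbeat, cue jitter, each channel's noise).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 250,
                              n_trials_left = 100, n_trials_right = 100,
                              trial_period = 8,
                              ibi_mean = 0.9, ibi_sd = 0.05,
                              systole_fraction = 0.35,
                              alpha_freq = 10, beta_freq = 20,
                              erd_depth_contra_diastole = 0.5,
                              erd_depth_contra_systole = 0.2,
                              erd_depth_ipsi = 0.2,
                              erd_window = c(0.5, 2),
                              emg_burst_gain_ipsi = 1,
                              emg_burst_gain_contra = 0.25,
                              emg_phase_gain_diastole = 1.3,
                              artifact_gain = 0.2,
                              noise_sd = 1,
                              task = c("MI", "ME"),
                              lead_in = 6,
                              session_duration = NULL,
                              seed = 1L) {
  task <- match.arg(task)
  n_trials <- n_trials_left + n_trials_right
  if (is.null(session_duration))
    session_duration <- 2 * lead_in + n_trials * trial_period
  cfg <- list(sampling_rate = sampling_rate, n_trials_left = n_trials_left,
              n_trials_right = n_trials_right, trial_period = trial_period,
              ibi_mean = ibi_mean, ibi_sd = ibi_sd,
              systole_fraction = systole_fraction,
              alpha_freq = alpha_freq, beta_freq = beta_freq,
              erd_depth_contra_diastole = erd_depth_contra_diastole,
              erd_depth_contra_systole = erd_depth_contra_systole,
              erd_depth_ipsi = erd_depth_ipsi, erd_window = erd_window,
              emg_burst_gain_ipsi = emg_burst_gain_ipsi,
              emg_burst_gain_contra = emg_burst_gain_contra,
              emg_phase_gain_diastole = emg_phase_gain_diastole,
              artifact_gain = artifact_gain, noise_sd = noise_sd,
              task = task, lead_in = lead_in,
              session_duration = session_duration, seed = as.integer(seed))
  pos <- c("sampling_rate", "trial_period", "ibi_mean", "session_duration",
           "noise_sd")
  for (p in pos) if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
    stop(sprintf("'%s' must be strictly positive", p))
  if (ibi_sd < 0) stop("'ibi_sd' must be non-negative")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("'systole_fraction' must lie in (0, 1)")
  depths <- c(erd_depth_contra_diastole, erd_depth_contra_systole,
              erd_depth_ipsi)
  if (any(depths < 0 | depths > 1))
    stop("suppression depths must lie in [0, 1]")
  if (length(erd_window) != 2 || diff(erd_window) <= 0)
    stop("'erd_window' must be an increasing (start, end) pair")
  if (n_trials < 1) stop("at least one trial is required")
  if (2 * lead_in + n_trials * trial_period > session_duration + 1e-9)
    stop("cues do not fit inside 'session_duration' at 'trial_period' spacing")
  # IBIs are truncated at +/- 3 SD; beats must not overlap the beat templates
  if (ibi_mean - 3 * ibi_sd <= 0.35)
    stop("'ibi_sd' too large: beats would overlap (ibi_mean - 3*ibi_sd <= 0.35 s)")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic session configuration\n")
  cat(sprintf("  %d left + %d right %s trials, %.3g s apart, fs = %g Hz\n",
              x$n_trials_left, x$n_trials_right, x$task, x$trial_period,
              x$sampling_rate))
  cat(sprintf("  IBI %.3g +/- %.3g s, systole fraction %.2f\n",
              x$ibi_mean, x$ibi_sd, x$systole_fraction))
  cat(sprintf("  ERD depths contra (diastole/systole) %.2f/%.2f, ipsi %.2f\n",
              x$erd_depth_contra_diastole, x$erd_depth_contra_systole,
              x$erd_depth_ipsi))
  invisible(x)
}

# derive k independent substream seeds from the master seed
.substream_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

# gaussian bump added in place over +/- 5 sd
.add_bump <- function(x, fs, center, sd, amp) {
  n <- length(x)
  i0 <- max(1L, floor((center - 5 * sd) * fs) + 1L)
  i1 <- min(n, ceiling((center + 5 * sd) * fs) + 1L)
  if (i1 < i0) return(x)
  tt <- (seq.int(i0, i1) - 1) / fs
  x[i0:i1] <- x[i0:i1] + amp * exp(-(tt - center)^2 / (2 * sd^2))
  x
}

# template timing constants (s): stereotyped P-QRS-T gaussian bumps.
# The T bump has sd .T_SD and is centered 2*sd before the programmed T-wave
# offset, so the tangent through the steepest point of its descending limb
# crosses baseline exactly at the offset.
.R_SD <- 0.012
.P_SD <- 0.02
.T_SD <- 0.05
.P_LEAD <- 0.16
.T_AMP <- 0.3
.P_AMP <- 0.12

#' Simulate a stereotyped ECG trace with known event times
#'
#' Beats are sums of Gaussian P/R/T bumps placed at R times drawn with
#' IBI ~ Normal(`ibi_mean`, `ibi_sd`) truncated at +/- 3 SD. The T-wave offset
#' of beat k is placed exactly at `R_k + systole_fraction * IBI_k`.
#'
#' @param config a [simulation_config()].
#' @return list with `ecg` (numeric trace), `r_times`, `t_offsets` (one per
#'   beat that has a successor), `ibis`, and `fs`. These event times are the
#'   generator's ground truth.
#' @export
simulate_ecg <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sampling_rate
  dur <- config$session_duration
  n_max <- ceiling(dur / max(config$ibi_mean - 3 * config$ibi_sd, 0.35)) + 2L
  ibis <- rnorm(n_max, config$ibi_mean, config$ibi_sd)
  if (config$ibi_sd > 0) {
    bad <- abs(ibis - config$ibi_mean) > 3 * config$ibi_sd
    while (any(bad)) {
      ibis[bad] <- rnorm(sum(bad), config$ibi_mean, config$ibi_sd)
      bad <- abs(ibis - config$ibi_mean) > 3 * config$ibi_sd
    }
  }
  r_times <- cumsum(c(0.5, ibis))
  r_times <- r_times[r_times < dur - 0.5]
  nb <- length(r_times)
  ibis <- diff(r_times)
  t_offsets <- r_times[-nb] + config$systole_fraction * ibis

  ecg <- numeric(round(dur * fs))
  for (k in seq_len(nb)) {
    ecg <- .add_bump(ecg, fs, r_times[k], .R_SD, 1)
    ecg <- .add_bump(ecg, fs, r_times[k] - .P_LEAD, .P_SD, .P_AMP)
    if (k < nb)
      ecg <- .add_bump(ecg, fs, t_offsets[k] - 2 * .T_SD, .T_SD, .T_AMP)
  }
  list(ecg = ecg, r_times = r_times, t_offsets = t_offsets, ibis = ibis,
       fs = fs)
}

#' Simulate a full coupled session
#'
#' Produces four region-level neural channels (M1/S1 by hemisphere), one ECG
#' lead and two EMG channels, together with the cue table and the full ground
#' truth. Neural channels are pink noise plus alpha and beta oscillators whose
#' amplitude drops by the programmed depth inside `erd_window` after each cue
#' (the contralateral depth depends on the cue's true cardiac phase; the
#' ipsilateral depth is fixed), plus `artifact_gain` times the ECG. EMG
#' channels are baseline noise plus a post-cue burst with ipsilateral gain
#' exceeding the contralateral one, multiplied by `emg_phase_gain_diastole`
#' when the cue falls in diastole. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `recording` (a `physio_recording`), `cues` (data.frame
#'   onset_s / side / task) and `truth` (ground-truth cardiac events, per-cue
#'   phase and angle, per-trial programmed depths, artifact gain).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sampling_rate
  if (diff(config$erd_window) > 5 ||
      config$erd_window[2] > config$trial_period)
    stop("'erd_window' exceeds the epoch span")
  seeds <- .substream_seeds(config$seed, 10L)

  set.seed(seeds[1]); ecg_sim <- simulate_ecg(config)
  n_samp <- length(ecg_sim$ecg)
  tt <- (seq_len(n_samp) - 1) / fs

  # cue onsets: trial grid jittered uniformly +/- 0.25 s so the cue phase is
  # effectively uniform on the cardiac cycle; sides randomly interleaved
  set.seed(seeds[2])
  n_trials <- config$n_trials_left + config$n_trials_right
  onsets <- config$lead_in + (seq_len(n_trials) - 1) * config$trial_period +
    runif(n_trials, -0.25, 0.25)
  sides <- sample(rep(c("left", "right"),
                      c(config$n_trials_left, config$n_trials_right)))
  cues <- data.frame(onset_s = onsets, side = sides, task = config$task,
                     stringsAsFactors = FALSE)

  truth_events <- list(r_times = ecg_sim$r_times,
                       t_offsets = ecg_sim$t_offsets)
  phase <- label_cue_phase(onsets, truth_events)
  angle <- cue_angle(onsets, truth_events)

  # per-trial programmed suppression depth of the contralateral hemisphere
  depth_contra <- ifelse(phase == "diastole",
                         config$erd_depth_contra_diastole,
                         config$erd_depth_contra_systole)
  depth_contra[is.na(phase)] <- config$erd_depth_contra_systole

  # amplitude envelopes per hemisphere with 0.1 s linear ramps
  env_for_hemi <- function(hemi) {
    env <- rep(1, n_samp)
    ramp <- max(1L, round(0.1 * fs))
    for (i in seq_len(n_trials)) {
      contra <- (sides[i] == "left" && hemi == "rh") ||
        (sides[i] == "right" && hemi == "lh")
      depth <- if (contra) depth_contra[i] else config$erd_depth_ipsi
      if (depth <= 0) next
      i0 <- round((onsets[i] + config$erd_window[1]) * fs) + 1L
      i1 <- round((onsets[i] + config$erd_window[2]) * fs)
      if (i0 < 1L || i1 > n_samp || i1 <= i0) next
      env[i0:i1] <- 1 - depth
      dn <- min(ramp, i0 - 1L)
      if (dn > 0)
        env[(i0 - dn):(i0 - 1L)] <- 1 - depth * seq_len(dn) / (dn + 1)
      up <- min(ramp, n_samp - i1)
      if (up > 0)
        env[(i1 + 1L):(i1 + up)] <- 1 - depth * rev(seq_len(up)) / (up + 1)
    }
    env
  }
  env <- list(lh = env_for_hemi("lh"), rh = env_for_hemi("rh"))

  data <- matrix(0, n_samp, length(ALL_CHANNELS),
                 dimnames = list(NULL, ALL_CHANNELS))
  for (j in seq_along(NEURAL_CHANNELS)) {
    ch <- NEURAL_CHANNELS[j]
    hemi <- sub("^.*-", "", ch)
    set.seed(seeds[2 + j])
    phi <- runif(2, 0, 2 * pi)
    osc <- env[[hemi]] * (sin(2 * pi * config$alpha_freq * tt + phi[1]) +
                            sin(2 * pi * config$beta_freq * tt + phi[2]))
    data[, ch] <- .pink_noise(n_samp, config$noise_sd) + osc +
      config$artifact_gain * ecg_sim$ecg
  }
  data[, "ECG"] <- ecg_sim$ecg

  # EMG: white baseline noise + enveloped white-noise burst after each cue
  burst_env <- function(n) {       # Hann window
    0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  }
  for (side_ch in c("left", "right")) {
    set.seed(seeds[if (side_ch == "left") 7L else 8L])
    emg <- rnorm(n_samp, 0, 0.2)
    for (i in seq_len(n_trials)) {
      i0 <- round((onsets[i] + config$erd_window[1]) * fs) + 1L
      i1 <- round((onsets[i] + config$erd_window[2]) * fs)
      if (i0 < 1L || i1 > n_samp || i1 <= i0) next
      gain <- if (sides[i] == side_ch) config$emg_burst_gain_ipsi else
        config$emg_burst_gain_contra
      if (!is.na(phase[i]) && phase[i] == "diastole")
        gain <- gain * config$emg_phase_gain_diastole
      nwin <- i1 - i0 + 1L
      emg[i0:i1] <- emg[i0:i1] + gain * burst_env(nwin) * rnorm(nwin)
    }
    data[, paste0("EMG-", side_ch)] <- emg
  }

  recording <- physio_recording(data, fs)
  truth <- list(r_times = ecg_sim$r_times, t_offsets = ecg_sim$t_offsets,
                ibis = ecg_sim$ibis, phase = phase,
                theta = angle$theta_rad, depth_contra = depth_contra,
                depth_ipsi = config$erd_depth_ipsi,
                artifact_gain = config$artifact_gain, seed = config$seed)
  list(recording = recording, cues = cues, truth = truth)
}

#' Simulate a multi-subject study
#'
#' Generates one session per subject from a shared configuration, with
#' subject-specific heart rates (the inter-beat interval mean is jittered by
#' +/- 0.05 s across subjects, clipped to stay valid) and independent seeds
#' derived from `seed`.
#'
#' @param n_subjects number of subjects.
#' @param config base [simulation_config()].
#' @param seed master seed for the study.
#' @return list of session objects as returned by [simulate_session()].
#' @export
simulate_study <- function(n_subjects, config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"), n_subjects >= 1)
  seeds <- .substream_seeds(seed, n_subjects + 1L)
  set.seed(seeds[n_subjects + 1L])
  ibi_jit <- runif(n_subjects, -0.05, 0.05)
  lapply(seq_len(n_subjects), function(s) {
    cfg <- config
    cfg$ibi_mean <- max(config$ibi_mean + ibi_jit[s],
                        0.36 + 3 * config$ibi_sd)
    cfg$seed <- seeds[s]
    simulate_session(cfg)
  })
}

#' Multichannel physiological recording container
#'
#' @param data numeric matrix, samples by channels (named columns).
#' @param fs sampling rate, Hz.
#' @return object of class `physio_recording`.
#' @export
physio_recording <- function(data, fs) {
  stopifnot(is.matrix(data), !is.null(colnames(data)), fs > 0)
  structure(list(data = data, fs = fs,
                 channels = colnames(data),
                 duration = nrow(data) / fs),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("physio_recording: %d channels x %.1f s at %g Hz\n",
              ncol(x$data), x$duration, x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. Used to program angular clustering of
#' selected trials in recovery simulations (`kappa = 0` falls back to the
#' uniform distribution on the circle).
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter (>= 0).
#' @return angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}
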