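# End-to-end orchestration: ties the cardiac, spectral, EMG, group-statistics
# and circular stages into a reproducible run over a list of subject sessions.

#' Pipeline run configuration
#'
#' @param window analysis window (start, end) s post-cue; the primary window
#'   is 0.5--2 s, an exploratory full-epoch mode uses 0.5--4 s.
#' @param epoch_window epoch window relative to the cue, s.
#' @param baseline baseline window for z-scoring, s.
#' @param freqs wavelet frequencies, Hz.
#' @param n_cycles Morlet cycles.
#' @param bands named list of band edges, Hz.
#' @param n_perm permutations for the timewise tests.
#' @param q FDR level.
#' @param n_control_runs number of trial-count-balancing control runs.
#' @param percentiles suppression-index selection percentiles.
#' @param mc_perm Monte-Carlo permutations for the circular null.
#' @param weights group Rayleigh weighting, `"unit"` or `"rbar"`.
#' @param seed master seed; fanned out into independent substreams for the
#'   permutation tests, control draws and Monte-Carlo null.
#' @return list of class `run_config`.
#' @export
run_config <- function(window = c(0.5, 2), epoch_window = c(-1, 4),
                       baseline = c(-0.5, 0), freqs = 8:30, n_cycles = 5,
                       bands = list(alpha = c(8, 13), beta = c(14, 30)),
                       n_perm = 500, q = 0.05, n_control_runs = 10,
                       percentiles = c(50, 75, 90), mc_perm = 1000,
                       weights = c("unit", "rbar"), seed = 1L) {
  weights <- match.arg(weights)
  stopifnot(length(window) == 2, diff(window) > 0,
            window[1] >= epoch_window[1], window[2] <= epoch_window[2],
            n_perm >= 1, q > 0, q < 1, n_control_runs >= 0, mc_perm >= 1)
  structure(list(window = window, epoch_window = epoch_window,
                 baseline = baseline, freqs = freqs, n_cycles = n_cycles,
                 bands = bands, n_perm = n_perm, q = q,
                 n_control_runs = n_control_runs, percentiles = percentiles,
                 mc_perm = mc_perm, weights = weights,
                 seed = as.integer(seed)),
            class = "run_config")
}

# subject-level feature extraction: everything downstream group stats need
.process_subject <- function(session, config) {
  rec <- session$recording
  fs <- rec$fs
  ecg_f <- preprocess_ecg(rec$data[, "ECG"], fs)
  ev <- cardiac_events(ecg_f, fs)
  cues <- annotate_cues(session$cues, ev)

  # neural epochs, cardiac-field artifact removed by regression on the ECG
  rec_f <- rec
  rec_f$data[, "ECG"] <- ecg_f
  epochs <- epoch_recording(rec_f, cues, config$epoch_window,
                            channels = c(NEURAL_CHANNELS, "ECG"))
  ecg_ep <- epochs$data[, "ECG", , drop = TRUE]
  if (is.null(dim(ecg_ep))) ecg_ep <- matrix(ecg_ep, nrow = 1)
  neural <- epochs$data[, NEURAL_CHANNELS, , drop = FALSE]
  neural <- regress_cardiac_artifact(neural, ecg_ep)
  nep <- epochs
  nep$data <- neural
  nep$channels <- NEURAL_CHANNELS

  tfr <- morlet_power(nep, freqs = config$freqs, n_cycles = config$n_cycles)
  z <- baseline_zscore(tfr, baseline = config$baseline)
  bps <- band_average(z, bands = config$bands)

  # EMG envelopes epoched with the same cue table
  env <- rec$data[, EMG_CHANNELS, drop = FALSE]
  for (ch in EMG_CHANNELS) env[, ch] <- preprocess_emg(rec$data[, ch], fs)
  env_rec <- physio_recording(env, fs)
  emg_ep <- epoch_recording(env_rec, cues, config$epoch_window)
  emg <- split_ipsi_contra(emg_ep)

  list(events = ev, cues = bps$info, bps = bps, emg = emg,
       ecg_epochs = list(data = ecg_ep, t = epochs$t, info = epochs$info),
       mean_ibi = mean(ev$ibis))
}

# mean over a set of trial rows of a trials x samples matrix
.trial_mean <- function(m, rows) {
  if (length(rows) == 0) return(rep(NA_real_, ncol(m)))
  colMeans(m[rows, , drop = FALSE])
}

# paired timewise test dropping subjects without trials in a subset
.paired_test <- function(ipsi, contra, times, config) {
  ok <- complete.cases(ipsi) & complete.cases(contra)
  if (!all(ok))
    message(sum(!ok), " subject(s) dropped from a contrast (no trials)")
  timewise_perm_test(ipsi[ok, , drop = FALSE], contra[ok, , drop = FALSE],
                     times, n_perm = config$n_perm, q = config$q)
}

# contiguous range of significant times, NULL if none
.sig_range <- function(test) {
  if (!any(test$significant)) return(NULL)
  rng <- range(test$times[test$significant])
  # include the sample step so the window has positive length
  c(rng[1], rng[2] + diff(test$times[1:2]))
}

#' Run the full phase-resolved analysis over a group of sessions
#'
#' Executes, per subject: ECG delineation, cue phase/angle labelling,
#' artifact regression, Morlet band power, EMG envelopes; then, at the group
#' level: ECG sanity contrasts (left- vs right-cue ECG waveforms), EMG
#' ipsilateral-vs-contralateral and diastole-vs-systole contrasts, neural
#' laterality contrasts on all trials and on the systole-/diastole-cued
#' subsets, trial-count-balancing control runs, the suppression-index
#' circular analysis with its Monte-Carlo null, and the systole-overlap
#' summary. Every statistic is reproducible from (sessions, config).
#'
#' @param sessions list of sessions (each with `recording` and `cues`), e.g.
#'   from [simulate_study()] or loaded with [read_session()].
#' @param config a [run_config()].
#' @return a nested report list (class `phase_report`).
#' @export
run_pipeline <- function(sessions, config = run_config()) {
  stopifnot(inherits(config, "run_config"), length(sessions) >= 5)
  seeds <- .substream_seeds(config$seed, 4L)
  subjects <- lapply(sessions, .process_subject, config = config)
  ns <- length(subjects)
  t_axis <- subjects[[1]]$bps$t
  tsel <- t_axis >= config$window[1] & t_axis < config$window[2]
  times <- t_axis[tsel]
  regions <- unique(sub("-(lh|rh)$", "",
                        grep("-(lh|rh)$", subjects[[1]]$bps$channels,
                             value = TRUE)))
  bands <- names(config$bands)

  subsets <- c("all", "systole", "diastole")
  subset_rows <- function(subj, subset) {
    ph <- subj$cues$phase
    switch(subset, all = which(!is.na(ph)),
           systole = which(!is.na(ph) & ph == "systole"),
           diastole = which(!is.na(ph) & ph == "diastole"))
  }

  # ---- neural laterality contrasts -----------------------------------------
  set.seed(seeds[1])
  neural <- list()
  lat_cache <- list()
  for (rg in regions) for (bd in bands) {
    key <- paste(rg, bd, sep = ".")
    lat_cache[[key]] <- lapply(subjects, function(s)
      laterality_traces(s$bps, rg, bd))
    for (ss in subsets) {
      ipsi <- t(vapply(seq_len(ns), function(i)
        .trial_mean(lat_cache[[key]][[i]]$ipsi[, tsel, drop = FALSE],
                    subset_rows(subjects[[i]], ss)),
        numeric(sum(tsel))))
      contra <- t(vapply(seq_len(ns), function(i)
        .trial_mean(lat_cache[[key]][[i]]$contra[, tsel, drop = FALSE],
                    subset_rows(subjects[[i]], ss)),
        numeric(sum(tsel))))
      neural[[key]][[ss]] <- .paired_test(ipsi, contra, times, config)
    }
  }

  # ---- control runs: subsample diastole / all pools to the systole count ---
  set.seed(seeds[2])
  control <- list()
  if (config$n_control_runs > 0) {
    draws <- lapply(seq_len(ns), function(i) {
      n_sys <- length(subset_rows(subjects[[i]], "systole"))
      n_sys <- max(n_sys, 1L)
      list(diastole = balanced_control_runs(
             subset_rows(subjects[[i]], "diastole"), n_sys,
             config$n_control_runs),
           all = balanced_control_runs(
             subset_rows(subjects[[i]], "all"), n_sys,
             config$n_control_runs))
    })
    for (rg in regions) for (bd in bands) {
      key <- paste(rg, bd, sep = ".")
      for (pool in c("diastole", "all")) {
        runs <- lapply(seq_len(config$n_control_runs), function(r) {
          ipsi <- t(vapply(seq_len(ns), function(i)
            .trial_mean(lat_cache[[key]][[i]]$ipsi[, tsel, drop = FALSE],
                        draws[[i]][[pool]][[r]]), numeric(sum(tsel))))
          contra <- t(vapply(seq_len(ns), function(i)
            .trial_mean(lat_cache[[key]][[i]]$contra[, tsel, drop = FALSE],
                        draws[[i]][[pool]][[r]]), numeric(sum(tsel))))
          tw <- .paired_test(ipsi, contra, times, config)
          list(n_significant = sum(tw$significant),
               sig_range = .sig_range(tw), delta_dep = tw$delta_dep)
        })
        control[[key]][[pool]] <- runs
      }
    }
  }

  # ---- EMG contrasts -------------------------------------------------------
  set.seed(seeds[3])
  emg <- NULL
  if (!is.null(subjects[[1]]$emg)) {
    emg_t <- subjects[[1]]$emg$t
    esel <- emg_t >= config$window[1] & emg_t < config$window[2]
    etimes <- emg_t[esel]
    ipsi_all <- t(vapply(subjects, function(s)
      colMeans(s$emg$ipsi[, esel, drop = FALSE]), numeric(sum(esel))))
    contra_all <- t(vapply(subjects, function(s)
      colMeans(s$emg$contra[, esel, drop = FALSE]), numeric(sum(esel))))
    phase_mats <- lapply(c("diastole", "systole"), function(ph) {
      t(vapply(subjects, function(s) {
        rows <- which(!is.na(s$emg$info$phase) & s$emg$info$phase == ph)
        colMeans(s$emg$ipsi[rows, esel, drop = FALSE])
      }, numeric(sum(esel))))
    })
    emg <- list(
      ipsi_vs_contra = .paired_test(ipsi_all, contra_all, etimes, config),
      ipsi_diastole_vs_systole = .paired_test(phase_mats[[1]],
                                              phase_mats[[2]], etimes,
                                              config))
  }

  # ---- ECG sanity contrast: left-cue vs right-cue waveforms ----------------
  ecg_mats <- lapply(c("left", "right"), function(sd_) {
    t(vapply(subjects, function(s) {
      rows <- which(s$ecg_epochs$info$side == sd_)
      colMeans(s$ecg_epochs$data[rows, , drop = FALSE])
    }, numeric(length(subjects[[1]]$ecg_epochs$t))))
  })
  ecg_sanity <- timewise_perm_test(ecg_mats[[1]], ecg_mats[[2]],
                                   subjects[[1]]$ecg_epochs$t,
                                   n_perm = config$n_perm, q = config$q)
  mean_ibis <- vapply(subjects, `[[`, 1, "mean_ibi")

  # ---- circular analysis of the suppression index --------------------------
  set.seed(seeds[4])
  circular <- list()
  for (rg in regions) for (bd in bands) {
    key <- paste(rg, bd, sep = ".")
    win <- .sig_range(neural[[key]]$all)
    fallback <- is.null(win)
    if (fallback) win <- config$window
    for (pct in config$percentiles) {
      subj_angles <- lapply(subjects, function(s) {
        idx <- suppression_index(s$bps, rg, bd, win)
        keep <- select_trials(idx, pct)
        th <- s$cues$theta_rad[keep]
        th[is.finite(th)]
      })
      counts <- vapply(subj_angles, length, 1L)
      gr <- group_rayleigh(subj_angles, weights = config$weights)
      null_z <- monte_carlo_null(pmax(counts, 1L), n_perm = config$mc_perm)
      circular[[key]][[paste0("p", pct)]] <- list(
        window = win, window_fallback = fallback, percentile = pct,
        group = gr, monte_carlo_p = empirical_p(gr$group$Z, null_z),
        n_selected = counts)
    }
  }

  # ---- overlap of diastole-cued significant window with the next systole ---
  overlap <- list()
  for (rg in regions) for (bd in bands) {
    key <- paste(rg, bd, sep = ".")
    win <- .sig_range(neural[[key]]$diastole)
    if (is.null(win)) { overlap[[key]] <- NULL; next }
    per_subj <- vapply(seq_len(ns), function(i) {
      cues_i <- subjects[[i]]$cues
      dia <- cues_i$onset_s[!is.na(cues_i$phase) &
                              cues_i$phase == "diastole"]
      systole_overlap_summary(win, subjects[[i]]$events, dia)$mean
    }, numeric(1))
    overlap[[key]] <- list(window = win, per_subject_s = per_subj,
                           mean_s = mean(per_subj, na.rm = TRUE))
  }

  structure(list(config = config, n_subjects = ns,
                 ecg = list(left_vs_right = ecg_sanity,
                            mean_ibis = mean_ibis),
                 emg = emg, neural = neural, control = control,
                 circular = circular, overlap = overlap,
                 version = as.character(utils::packageVersion("cardiophase"))),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("phase_report: %d subjects, window %.2f-%.2f s, %d permutations\n",
              x$n_subjects, x$config$window[1], x$config$window[2],
              x$config$n_perm))
  for (key in names(x$neural)) {
    cat(sprintf("  %s laterality: ", key))
    cat(vapply(names(x$neural[[key]]), function(ss) {
      tw <- x$neural[[key]][[ss]]
      sprintf("%s %d sig", ss, sum(tw$significant))
    }, character(1)), sep = "; ")
    cat("\n")
  }
  invisible(x)
}
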