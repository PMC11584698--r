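test_that("ECG band-pass removes DC, attenuates 50 Hz, and is idempotent in band", {
  fs <- 250
  tt <- seq(0, 60, by = 1 / fs)
  set.seed(5)
  qrs <- numeric(length(tt))
  qrs[seq(125, length(tt), by = round(0.8 * fs))] <- 1
  x <- 3 + qrs + 0.5 * sin(2 * pi * 50 * tt) + 0.3 * sin(2 * pi * 10 * tt)
  y <- preprocess_ecg(x, fs)
  expect_lt(abs(mean(y)), 0.02)                       # DC gone
  expect_lt(band_power_at(y, fs, 50) / band_power_at(x, fs, 50), 0.1)
  # second pass changes almost nothing inside the passband
  y2 <- preprocess_ecg(y, fs)
  inband <- fir_filter(y - y2, fs, low = 0.5, high = 35)
  expect_lt(sqrt(mean(inband^2)) / sqrt(mean(y^2)), 0.01)
  expect_error(preprocess_ecg(c(1, NA, 2), fs), "NA")
  expect_error(preprocess_ecg(rnorm(100), 60), "sampling rate")
})

test_that("R peaks are recovered exactly on noise-free ECG, either polarity", {
  ses <- get_small_session()
  fs <- ses$recording$fs
  ecg_f <- get_small_ecg_filtered()
  r <- detect_r_peaks(ecg_f, fs)
  expect_length(r, length(ses$truth$r_times))
  expect_lt(max(abs(r - ses$truth$r_times)) * fs, 1 + 1e-9)
  r_flip <- detect_r_peaks(-ecg_f, fs)
  expect_equal(r_flip, r)
  expect_error(detect_r_peaks(rep(0, 10000), fs), "beats")
})

test_that("T-wave offsets match ground truth within 15 ms and stay inside the beat", {
  ses <- get_small_session()
  fs <- ses$recording$fs
  ev <- get_small_events()
  expect_length(ev$t_offsets, length(ev$r_times) - 1)
  expect_lt(max(abs(ev$t_offsets - ses$truth$t_offsets), na.rm = TRUE), 0.015)
  ok <- !is.na(ev$t_offsets)
  expect_true(all(ev$t_offsets[ok] > ev$r_times[-length(ev$r_times)][ok]))
  expect_true(all(ev$t_offsets[ok] < ev$r_times[-1][ok]))
})

test_that("beats without a T bump are flagged missing, not fabricated", {
  fs <- 250
  # R spikes only (gaussian bumps), no T waves at all
  r_true <- seq(0.5, 19.5, by = 0.8)
  ecg <- numeric(20 * fs)
  tt <- (seq_along(ecg) - 1) / fs
  for (r in r_true) ecg <- ecg + exp(-(tt - r)^2 / (2 * 0.012^2))
  t_off <- detect_t_offsets(ecg, r_true, fs)
  expect_true(all(is.na(t_off)))
  expect_error(detect_t_offsets(ecg, r_true[1], fs), "at least 2")
})

test_that("cue phase labels follow the half-open systole/diastole convention", {
  ev <- list(r_times = c(0, 0.9, 1.8), t_offsets = c(0.3, 1.2))
  expect_equal(label_cue_phase(0.05, ev), "systole")    # R + 50 ms
  expect_equal(label_cue_phase(0.35, ev), "diastole")   # past T offset
  expect_equal(label_cue_phase(0.3, ev), "diastole")    # exactly at T offset
  expect_equal(label_cue_phase(0, ev), "systole")       # exactly at R
  expect_true(is.na(label_cue_phase(2.5, ev)))          # past last beat
  # labels partition all labelled cues
  ses <- get_small_session()
  ph <- label_cue_phase(ses$cues$onset_s, get_small_events())
  expect_true(all(ph[!is.na(ph)] %in% c("systole", "diastole")))
})

test_that("cue angles implement the normalized-latency rule with 4-beat IBI", {
  r <- c(cumsum(c(0.5, 0.8, 0.8, 1.0, 1.0)))    # 5 R peaks
  ev <- list(r_times = r)
  # zero latency
  expect_equal(cue_angle(r[5], ev)$theta_rad, 0)
  # previous four IBIs {0.8, 0.8, 1.0, 1.0}: IBI_i = 0.9, C - R = 0.45 -> pi
  a <- cue_angle(r[5] + 0.45, ev)
  expect_equal(a$ibi_used_s, 0.9)
  expect_equal(a$theta_rad, pi)
  # latency beyond one averaged cycle wraps: 2*pi*(1/0.9) mod 2*pi
  ev2 <- list(r_times = c(r, r[5] + 1.5))
  a2 <- cue_angle(r[5] + 1.0, ev2)
  expect_equal(a2$theta_rad, (2 * pi / 0.9) %% (2 * pi), tolerance = 1e-12)
  # cue before the second R has no preceding interval
  expect_true(is.na(cue_angle(0.2, ev)$theta_rad))
})

test_that("angle below the systolic arc implies a systole label", {
  ses <- get_small_session()
  ev <- get_small_events()
  cues <- annotate_cues(ses$cues, ev)
  ok <- !is.na(cues$phase) & is.finite(cues$theta_rad)
  k <- findInterval(cues$onset_s, ev$r_times)
  sys_arc <- 2 * pi * (ev$t_offsets[k] - ev$r_times[k]) / cues$ibi_used_s
  lab_sys <- cues$phase[ok] == "systole"
  below <- cues$theta_rad[ok] < 0.95 * sys_arc[ok]    # clear of the boundary
  expect_true(all(!below | lab_sys))
})

test_that("artifact regression recovers the clean signal and is idempotent", {
  set.seed(11)
  n_tr <- 8; n_s <- 2000
  s_clean <- array(rnorm(n_tr * 2 * n_s), c(n_tr, 2, n_s))
  ecg <- matrix(rnorm(n_tr * n_s), n_tr, n_s)
  contaminated <- s_clean
  for (ch in 1:2) contaminated[, ch, ] <- s_clean[, ch, ] + 0.4 * ecg
  cleaned <- regress_cardiac_artifact(contaminated, ecg)
  for (ch in 1:2) {
    expect_lt(abs(cor(as.vector(cleaned[, ch, ]), as.vector(ecg))), 0.02)
    resid <- cleaned[, ch, ] - s_clean[, ch, ]
    expect_lt(sqrt(mean(resid^2)) / sqrt(mean(s_clean[, ch, ]^2)), 0.05)
  }
  # nothing to remove when the artifact is absent
  cleaned0 <- regress_cardiac_artifact(s_clean, ecg)
  expect_lt(sqrt(mean((cleaned0 - s_clean)^2)) / sqrt(mean(s_clean^2)), 0.01)
  # second pass is a no-op
  twice <- regress_cardiac_artifact(cleaned, ecg)
  expect_lt(sqrt(mean((twice - cleaned)^2)) / sqrt(mean(cleaned^2)), 0.001)
  expect_error(regress_cardiac_artifact(contaminated,
                                        matrix(1, n_tr, n_s)),
               "zero-variance")
})
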