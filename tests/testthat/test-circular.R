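test_that("suppression index has the stated sign convention and arithmetic", {
  ses <- get_small_session()
  ev <- get_small_events()
  cues <- annotate_cues(ses$cues, ev)
  ep <- epoch_recording(ses$recording, cues, c(-1, 4),
                        channels = c("M1-lh", "M1-rh", "S1-lh", "S1-rh"))
  bps <- band_average(baseline_zscore(morlet_power(ep)))
  # synthetic band powers with known values override the computed ones
  man <- bps
  man$z[, , , ] <- 0
  lh <- match("M1-lh", man$channels); rh <- match("M1-rh", man$channels)
  # left-cued trial 1: ipsi = lh; set ipsi -1, contra -2 -> index +1
  man$info$side[1] <- "left"
  man$z[1, lh, "alpha", ] <- -1
  man$z[1, rh, "alpha", ] <- -2
  idx <- suppression_index(man, "M1", "alpha", c(0.5, 2))
  expect_equal(idx[1], 1)
  expect_equal(idx[2], 0)                       # identical traces
  # contra less suppressed than ipsi: negative index
  man$z[1, rh, "alpha", ] <- 0
  expect_equal(suppression_index(man, "M1", "alpha", c(0.5, 2))[1], -1)
  expect_error(suppression_index(man, "M1", "alpha", c(1, 1)), "window")
  # the real programmed effect yields mostly positive indices
  expect_gt(mean(suppression_index(bps, "M1", "alpha", c(0.5, 2)) > 0), 0.5)
})

test_that("percentile trial selection is sized correctly and nested", {
  idx <- seq_len(100) / 100                     # 100 distinct values
  s50 <- select_trials(idx, 50)
  s75 <- select_trials(idx, 75)
  s90 <- select_trials(idx, 90)
  expect_length(s50, 50)
  expect_length(s90, 10)
  expect_true(all(s90 %in% s75))
  expect_true(all(s75 %in% s50))
  expect_error(select_trials(idx[1:5], 50), "10 trials")
})

test_that("Rayleigh test behaves at the concentration extremes", {
  rt1 <- rayleigh_test(rep(1.3, 10))
  expect_equal(rt1$rbar, 1)
  expect_lt(rt1$p, 1e-3)
  expect_equal(rt1$mean_direction, 1.3)
  # perfectly uniform spacing: resultant vanishes
  rt0 <- rayleigh_test(seq(0, 2 * pi, length.out = 9)[1:8])
  expect_lt(rt0$rbar, 1e-12)
  expect_equal(rt0$p, 1)
  expect_error(rayleigh_test(c(0.1, 0.2)), "3 finite")
  # p decreases monotonically in rbar at fixed n
  ps <- vapply(seq(0, 0.9, by = 0.1), rayleigh_p, numeric(1), n = 29)
  expect_true(all(diff(ps) < 0))
})

test_that("group-level second-order test mirrors subject agreement", {
  # all subjects share a direction
  same <- replicate(6, 2.5 + 0.05 * rnorm(30), simplify = FALSE)
  g1 <- group_rayleigh(same)
  expect_lt(g1$group$p, 1e-3)
  expect_equal(g1$group$mean_direction, 2.5, tolerance = 0.1)
  # subject directions spread uniformly
  set.seed(41)
  spread <- lapply(seq(0, 2 * pi, length.out = 9)[1:8],
                   function(mu) mu + 0.05 * rnorm(30))
  g0 <- group_rayleigh(spread)
  expect_gt(g0$group$p, 0.5)
  # subjects with < 3 usable angles are dropped with a message
  expect_message(g2 <- group_rayleigh(c(same, list(c(1, NA, NA)))),
                 "dropped")
  expect_equal(g2$n_subjects, 6)
  expect_error(group_rayleigh(list(1:5 / 5, 1:5 / 5)), "3 subjects")
})

test_that("programmed angular clustering is recovered by the group chain", {
  recovered <- 0
  for (rep_i in 1:10) {
    set.seed(rep_i + 50)
    angles <- replicate(29, rvonmises(95, 4.0, 1), simplify = FALSE)
    g <- group_rayleigh(angles)
    dir_err <- abs(atan2(sin(g$group$mean_direction - 4),
                         cos(g$group$mean_direction - 4)))
    if (dir_err < 0.3 && g$group$p < 0.05) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("Monte-Carlo null has the add-one floor and count invariance", {
  null_z <- monte_carlo_null(rep(20, 8), n_perm = 400, seed = 3)
  expect_length(null_z, 400)
  expect_equal(empirical_p(max(null_z) + 1, null_z), 1 / 401)
  expect_equal(empirical_p(-1, null_z), 1)
  # the null distribution is insensitive to how trials spread over subjects
  a <- monte_carlo_null(c(5, 10, 20, 40, 80, 160), n_perm = 800, seed = 4)
  b <- monte_carlo_null(rep(35, 6), n_perm = 800, seed = 5)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
  expect_error(monte_carlo_null(c(0, 5, 5)), "trial_counts")
})

test_that("Monte-Carlo p-values are uniform under the null", {
  set.seed(44)
  counts <- rep(20, 8)
  draws <- 300
  ps <- vapply(seq_len(draws), function(i) {
    th <- lapply(counts, function(k) runif(k, 0, 2 * pi))
    obs <- group_rayleigh(th)$group$Z
    empirical_p(obs, monte_carlo_null(counts, n_perm = 200))
  }, numeric(1))
  # ties are expected: empirical p-values live on a 1/(n_perm+1) grid
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("window/systole overlap is an interval intersection per cue", {
  ev <- list(r_times = c(0.4, 1.3, 2.2), t_offsets = c(0.7, 1.6))
  # cue at 0.7 (diastole): next systole spans (0.6, 0.9) relative to the cue
  ov <- systole_overlap_summary(c(0.5, 1.9), ev, 0.7)
  expect_equal(ov$per_cue, 0.3)
  # significant window entirely inside the systolic interval
  ov2 <- systole_overlap_summary(c(0.65, 0.85), ev, 0.7)
  expect_equal(ov2$per_cue, 0.2)
  # disjoint window
  ov3 <- systole_overlap_summary(c(1.0, 1.4), ev, 0.7)
  expect_equal(ov3$per_cue, 0)
  # cue without a subsequent complete beat is skipped
  ov4 <- systole_overlap_summary(c(0.5, 1.9), ev, 1.9)
  expect_length(ov4$per_cue, 0)
  expect_true(is.na(ov4$mean))
})
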