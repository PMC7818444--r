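# Synthetic-data generators: determinism, spectral properties, and the
# noiseless generative/analysis consistency that anchors everything else.

test_that("stimulus generator: length, nonnegativity, band limit, determinism", {
  s <- generate_stimulus(176, 30, seed = 2)
  expect_length(s, 5280)
  expect_true(all(s >= 0))
  expect_identical(s, generate_stimulus(176, 30, seed = 2))
  expect_false(identical(s, generate_stimulus(176, 30, seed = 3)))
  # power above the 3 Hz cutoff is a tiny fraction of the power below
  expect_lt(power_ratio_above(s, 30, 3), 0.01)
  expect_error(generate_stimulus(-1, 30), "positive")
  expect_error(generate_stimulus(10, 30, cutoff_hz = 20), "Nyquist")
})

test_that("ground truth: unit-norm filters, stated peak lags, independent maps", {
  gt <- generate_ground_truth(n_channels = 96, n_components = 3, n_lags = 30)
  expect_equal(colSums(gt$true_temporal_filters^2), rep(1, 3))
  peaks <- apply(gt$true_temporal_filters, 2, which.max) - 1L
  expect_equal(peaks[1:2], c(6L, 12L))  # 200 and 400 ms at 30 Hz
  expect_equal(qr(gt$true_spatial_maps)$rank, 3L)
  gt1 <- generate_ground_truth(n_components = 1)
  expect_equal(ncol(gt1$true_spatial_maps), 1L)
  expect_equal(sum(gt1$true_temporal_filters^2), 1)
  gt_b <- generate_ground_truth(seed = 99)
  expect_false(isTRUE(all.equal(gt$true_spatial_maps, gt_b$true_spatial_maps)))
  expect_error(generate_ground_truth(n_channels = 4, n_components = 5),
               "n_components")
})

test_that("noiseless EEG equals the planted spatio-temporal convolution exactly", {
  s <- generate_stimulus(60, 30, seed = 7)
  gt <- quiet_truth(n_channels = 12, n_components = 2)
  eeg <- generate_eeg(s, gt, "a", seed = 1)
  sz <- (s - mean(s)) / sd(s)
  L <- nrow(gt$true_temporal_filters)
  U <- vapply(1:2, function(j) {
    y <- stats::filter(c(rep(0, L - 1), sz), gt$true_temporal_filters[, j], sides = 1)
    as.numeric(y[L:(length(sz) + L - 1)])
  }, numeric(length(sz)))
  expect_equal(eeg$data, gt$true_spatial_maps %*% t(U), tolerance = 1e-12)
  expect_error(generate_eeg(s, gt, "nope", seed = 1), "unknown condition")
})

test_that("alpha injection adds A^2/2 band power on central channels only", {
  s <- generate_stimulus(120, 30, seed = 3)
  gt0 <- generate_ground_truth(n_channels = 24, n_components = 1, seed = 5,
                               condition_gains = c(a = 1),
                               alpha_amplitude = c(a = 0), noise_sd = 5,
                               artifact_rate = 0, blink_rate = 0)
  gt2 <- gt0
  gt2$alpha_amplitude <- c(a = 2)
  e0 <- generate_eeg(s, gt0, "a", seed = 9)
  e2 <- generate_eeg(s, gt2, "a", seed = 9)
  cc <- gt0$central_channels[1]
  p0 <- alpha_power(e0)$power
  p2 <- alpha_power(e2)$power
  # sinusoid of amplitude 2 has mean square A^2/2 = 2
  expect_equal(p2[cc] - p0[cc], 2, tolerance = 0.15)
  off <- setdiff(seq_len(24), gt0$central_channels)
  expect_equal(p2[off], p0[off], tolerance = 1e-9)
  # spectral confinement: power outside 8-12 Hz changes by < 5%
  out_band <- alpha_power(e2, band = c(2, 6))$power
  out_band0 <- alpha_power(e0, band = c(2, 6))$power
  expect_lt(max(abs(out_band - out_band0) / out_band0), 0.05)
})

test_that("condition gain scales stimulus-locked variance quadratically", {
  s <- generate_stimulus(60, 30, seed = 11)
  gt <- quiet_truth(n_channels = 8, n_components = 1,
                    gains = c(lo = 1, hi = 1.25))
  e_lo <- generate_eeg(s, gt, "lo", seed = 4)
  e_hi <- generate_eeg(s, gt, "hi", seed = 4)
  ratio <- var(e_hi$data[1, ]) / var(e_lo$data[1, ])
  expect_equal(ratio, 1.25^2, tolerance = 1e-9)
})

test_that("cohort generator: trial counts, reproducibility, condition labels", {
  coh <- generate_cohort(n_subjects = 3, trials_per_condition = 2, seed = 5,
                         duration_s = 10, n_channels = 12, noise_sd = 5,
                         artifact_rate = 0, blink_rate = 0)
  expect_length(coh, 3)
  expect_equal(sum(vapply(coh, function(ss) length(ss$trials), numeric(1))),
               3 * 3 * 2)  # subjects x conditions x repeats
  conds <- vapply(coh[[1]]$trials, `[[`, "", "condition")
  expect_setequal(unique(conds), c("active", "sham", "passive"))
  coh2 <- generate_cohort(n_subjects = 3, trials_per_condition = 2, seed = 5,
                          duration_s = 10, n_channels = 12, noise_sd = 5,
                          artifact_rate = 0, blink_rate = 0)
  expect_equal(coh[[2]]$trials[[4]]$eeg$data, coh2[[2]]$trials[[4]]$eeg$data)
  # subject maps share shape but differ between subjects
  expect_false(isTRUE(all.equal(coh[[1]]$ground_truth$true_spatial_maps,
                                coh[[2]]$ground_truth$true_spatial_maps)))
  expect_equal(coh[[1]]$ground_truth$true_temporal_filters,
               coh[[2]]$ground_truth$true_temporal_filters)
  expect_error(generate_cohort(n_subjects = 1), "two subjects")
  expect_error(generate_cohort(n_subjects = 2,
                               conditions = data.frame(label = character(0),
                                                       gain = numeric(0),
                                                       alpha_amplitude = numeric(0))),
               "empty")
})

test_that("translating frames: exact shift, static case, speed proportionality", {
  fr <- generate_translating_frames(32, 48, 6, speed = 1, seed = 1)
  expect_equal(dim(fr$frames), c(6, 32, 48))
  # frame k+1 is frame k circularly shifted right by 1 px
  expect_equal(fr$frames[2, , c(2:48, 1)], fr$frames[1, , ], tolerance = 1e-10)
  fr0 <- generate_translating_frames(32, 48, 4, speed = 0, seed = 1)
  expect_equal(fr0$frames[3, , ], fr0$frames[1, , ])
  # mean true displacement doubles with speed
  fr2 <- generate_translating_frames(32, 48, 6, speed = 2, seed = 1)
  expect_equal(fr2$frames[2, , c(3:48, 1:2)], fr2$frames[1, , ], tolerance = 1e-10)
  expect_error(generate_translating_frames(8, 8, 1, 1), "two frames")
  expect_error(generate_translating_frames(8, 8, 4, -1), "speed")
})
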