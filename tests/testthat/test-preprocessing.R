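# EEG preprocessing chain: resampling, robust PCA, ocular regression,
# iterative rejection, and the assembled pipeline.

test_that("resampling: output length, DC removal, passband fidelity", {
  t5 <- (0:4999) / 500
  raw <- eeg_recording(rbind(sin(2 * pi * 5 * t5), 3 + 0 * t5), 500)
  out <- resample_and_highpass(raw, 30, 1)
  expect_equal(ncol(out$data), 300)
  expect_equal(out$rate, 30)
  mid <- 31:270  # exclude 1 s edges
  # 5 Hz unit sinusoid passes with amplitude within 5% (RMS-based estimate)
  expect_equal(sqrt(2 * mean(out$data[1, mid]^2)), 1, tolerance = 0.05)
  # DC-only channel is annihilated by the high-pass
  expect_lt(max(abs(out$data[2, mid])), 1e-6)
  expect_error(resample_and_highpass(raw, 600), "below")
})

test_that("robust PCA recovers a planted low-rank + sparse decomposition", {
  set.seed(1)
  U <- matrix(rnorm(96 * 3), 96)
  V <- matrix(rnorm(3 * 3000), 3)
  L0 <- U %*% V
  S0 <- matrix(0, 96, 3000)
  idx <- sample(length(S0), round(0.01 * length(S0)))
  S0[idx] <- sample(c(-50, 50), length(idx), replace = TRUE)
  rp <- robust_pca(L0 + S0, lam = 1)
  expect_lt(sqrt(sum((rp$L - L0)^2)) / sqrt(sum(L0^2)), 1e-3)
  expect_lt(sqrt(sum((rp$L + rp$S - L0 - S0)^2)) / sqrt(sum((L0 + S0)^2)), 1e-6)
  expect_true(rp$converged)
  # clean low-rank input: sparse part is negligible
  rp0 <- robust_pca(L0[, 1:500], lam = 1)
  expect_lt(sqrt(sum(rp0$S^2)) / sqrt(sum(L0[, 1:500]^2)), 1e-4)
  # additivity holds at the pipeline default weight too
  rp5 <- robust_pca(L0[1:32, 1:400] + S0[1:32, 1:400], lam = 0.5)
  expect_lt(sqrt(sum((rp5$L + rp5$S - L0[1:32, 1:400] - S0[1:32, 1:400])^2)) /
              sqrt(sum((L0[1:32, 1:400] + S0[1:32, 1:400])^2)), 1e-6)
  expect_error(robust_pca(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("ocular regressors are signed channel sums and capture planted blinks", {
  set.seed(2)
  X <- matrix(rnorm(10 * 200), 10)
  eeg <- eeg_recording(X, 30)
  oc <- build_ocular_regressors(eeg, list(
    list(list(1L, +1), list(2L, +1)),
    list(list(1L, +1), list(2L, -1)),
    list(list(3L, +1), list(4L, +1)),
    list(list(5L, +1), list(6L, -1))
  ))
  expect_equal(oc$signals[1, ], X[1, ] + X[2, ])
  expect_equal(oc$signals[2, ], X[1, ] - X[2, ])
  bad <- eeg
  bad$valid_channels[1] <- FALSE
  expect_error(build_ocular_regressors(bad, oc$construction), "rejected")

  # blink-carrying recording: the vertical virtual electrode tracks the blink
  s <- generate_stimulus(120, 30, seed = 5)
  gt <- generate_ground_truth(n_channels = 32, n_components = 1, noise_sd = 5,
                              artifact_rate = 0, blink_rate = 15,
                              blink_amplitude = 600,
                              alpha_amplitude = c(a = 0),
                              condition_gains = c(a = 1))
  eeg_b <- generate_eeg(s, gt, "a", seed = 6)
  blink <- attr(eeg_b, "blink_timecourse")
  oc_b <- build_ocular_regressors(eeg_b)
  expect_gt(abs(cor(oc_b$signals[3, ], blink)), 0.9)
})

test_that("regress_out projects cleanly, leaves orthogonal channels, is idempotent", {
  set.seed(3)
  n <- 500
  R <- matrix(rnorm(4 * n), 4)
  X <- rbind(R[1, ],                        # equals regressor 1
             rnorm(n))                      # independent channel
  eeg <- eeg_recording(X, 30)
  oc <- structure(list(signals = R, construction = NULL),
                  class = "ocular_regressors")
  out <- regress_out(eeg, oc)
  expect_lt(max(abs(out$data[1, ])), 1e-9)
  expect_gt(cor(out$data[2, ], X[2, ]), 0.99)
  out2 <- regress_out(out, oc)
  expect_equal(out2$data, out$data, tolerance = 1e-9)
  # rank-deficient regressor set is dropped with a warning
  oc_bad <- structure(list(signals = rbind(R[1, ], R[1, ], R[2, ], R[3, ]),
                           construction = NULL), class = "ocular_regressors")
  expect_warning(regress_out(eeg, oc_bad), "dependent")

  # planted mixture: channel = clean + 0.7 x blink -> residual decorrelated
  blink <- rep(0, n)
  blink[sort(sample(n - 6, 12))] <- 1
  blink <- as.numeric(stats::filter(blink, rep(1, 6), sides = 1) *
                        sin(2 * pi * seq_len(n) / 6))
  blink[is.na(blink)] <- 0
  clean_ch <- rnorm(n, sd = 0.05)
  mix <- eeg_recording(rbind(clean_ch + 0.7 * blink, rnorm(n, sd = 0.05)), 30)
  oc_blink <- structure(list(signals = rbind(blink, rnorm(n), rnorm(n), rnorm(n)),
                             construction = NULL), class = "ocular_regressors")
  res <- regress_out(mix, oc_blink)
  expect_lt(abs(cor(res$data[1, ], blink)), 0.05)
})

test_that("iterative rejection flags planted outliers and keeps clean data", {
  set.seed(4)
  X <- matrix(rnorm(32 * 2000), 32)
  eeg <- eeg_recording(X, 30)
  out <- iterative_rejection(eeg, n_sd = 4, n_iter = 3)
  # homogeneous Gaussian data: no channel rejected
  expect_true(all(out$valid_channels))
  # a channel scaled x10 is rejected in iteration 1
  X2 <- X; X2[7, ] <- X2[7, ] * 10
  out2 <- iterative_rejection(eeg_recording(X2, 30), 4, 1)
  expect_false(out2$valid_channels[7])
  expect_true(all(out2$valid_channels[-7]))
  # a single 500 uV spike invalidates itself and its neighbours
  X3 <- X; X3[3, 1000] <- 500
  out3 <- iterative_rejection(eeg_recording(X3, 30), 4, 3)
  expect_false(any(out3$valid_samples[3, 999:1001]))
  expect_equal(out3$data[3, 999:1001], c(0, 0, 0))
  # an aggressive threshold prunes channels but the data survive
  out4 <- iterative_rejection(eeg_recording(X2, 30), n_sd = 1, n_iter = 3)
  expect_lt(sum(out4$valid_channels), 32)
  expect_gte(sum(out4$valid_channels), 1)
})

test_that("preprocessing rescues SRC under heavy dense-spike contamination", {
  s <- generate_stimulus(120, 30, seed = 5)
  E <- temporal_embed(stimulus_feature(s, 30)$values, 30)
  gt <- generate_ground_truth(n_channels = 96, n_components = 2, noise_sd = 10,
                              artifact_rate = 15000, blink_rate = 15,
                              blink_amplitude = 300,
                              alpha_amplitude = c(a = 1),
                              condition_gains = c(a = 1))
  dirty <- generate_eeg(s, gt, "a", seed = 21)
  pp <- suppressWarnings(preprocess_eeg(dirty, target_rate = 30, rpca_lambda = 1))
  src_raw <- sum(suppressWarnings(fit_cca(E, dirty, 11))$rho)
  src_pp <- sum(suppressWarnings(fit_cca(E, pp, 11))$rho)
  expect_gt(src_pp, src_raw)
  # stage log records the configured order
  log <- attr(pp, "log")
  expect_named(log, c("resample", "robust_pca", "ocular", "rejection"))
})

test_that("robust PCA and rejection are near-identity on clean data", {
  # clean data carry no ocular activity, so the ocular stage is skipped and
  # the remaining stages are compared against the plain high-passed input
  s <- generate_stimulus(60, 30, seed = 8)
  gt <- generate_ground_truth(n_channels = 24, n_components = 1, noise_sd = 8,
                              artifact_rate = 0, blink_rate = 0,
                              alpha_amplitude = c(a = 1),
                              condition_gains = c(a = 1))
  eeg <- generate_eeg(s, gt, "a", seed = 9)
  pp <- suppressWarnings(preprocess_eeg(eeg, target_rate = 30, rpca_lambda = 1,
                                        frontal_sets = NA))
  b_hp <- signal::butter(4, 1 / 15, type = "high")
  ref <- t(apply(eeg$data, 1, function(ch) signal::filtfilt(b_hp, ch)))
  live <- which(pp$valid_channels)
  cors <- vapply(live, function(i) {
    v <- pp$valid_samples[i, ]
    cor(pp$data[i, v], ref[i, v])
  }, numeric(1))
  expect_gt(min(cors), 0.95)
})
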