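# The central CCA computation: embedding, oracle equivalence, noiseless
# identifiability, projection, pooling, and invariances.

test_that("temporal embedding builds causal zero-padded lag rows", {
  expect_equal(temporal_embed(c(1, 2, 3), 2),
               rbind(c(1, 0), c(2, 1), c(3, 2)))
  s <- rnorm(50)
  expect_equal(temporal_embed(s, 1), matrix(s, ncol = 1))
  # filter [1, -1] applied to the embedding is the first difference
  E <- temporal_embed(s, 2)
  expect_equal((E %*% c(1, -1))[-1], diff(s))
  expect_error(temporal_embed(1:3, 5), "shorter")
})

test_that("canonical correlations match the independent cancor oracle", {
  # 50 seeded small instances, untruncated EEG side
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    D <- sample(4:8, 1)
    L <- sample(2:4, 1)
    s <- rnorm(500)
    E <- temporal_embed(s, L)
    X <- matrix(rnorm(D * 500), D)
    X[1, ] <- X[1, ] + 0.5 * (E %*% rnorm(L))
    dec <- fit_cca(E, eeg_recording(X, 30), k_components = D)
    cc <- stats::cancor(E, t(X))
    worst <- max(worst, max(abs(dec$rho - cc$cor[seq_len(dec$K)])))
  }
  expect_lt(worst, 1e-8)
})

test_that("noiseless single-component session is identified exactly", {
  s <- generate_stimulus(176, 30, seed = 7)
  gt <- quiet_truth(n_channels = 16, n_components = 1)
  eeg <- generate_eeg(s, gt, "a", seed = 1)
  dec <- suppressWarnings(
    fit_cca(temporal_embed(stimulus_feature(s, 30)$values, 30), eeg, 11))
  expect_gte(dec$rho[1], 0.999)
  expect_gte(abs(cor(dec$temporal_filters[, 1], gt$true_temporal_filters[, 1])), 0.99)
  a_est <- dec$forward_models[, 1]
  a_true <- gt$true_spatial_maps[, 1]
  cosine <- sum(a_est * a_true) / sqrt(sum(a_est^2) * sum(a_true^2))
  expect_gte(abs(cosine), 0.99)
  # sign convention: peak temporal coefficient positive
  expect_gt(dec$temporal_filters[which.max(abs(dec$temporal_filters[, 1])), 1], 0)
})

test_that("total SRC sums components and projection reproduces training rho", {
  expect_equal(total_src(c(0.3, 0.2, 0.1))$total_src, 0.6)
  expect_equal(total_src(c(0.5))$total_src, 0.5)
  s <- generate_stimulus(60, 30, seed = 2)
  gt <- quiet_truth(n_channels = 10, n_components = 2)
  gt$noise_sd <- 5
  eeg <- generate_eeg(s, gt, "a", seed = 3)
  st <- stimulus_feature(s, 30)
  dec <- suppressWarnings(fit_cca(temporal_embed(st$values, 30), eeg, 8))
  pr <- project_src(dec, st, eeg)
  expect_equal(pr$per_component, dec$rho, tolerance = 1e-9)
  expect_equal(pr$total_src, sum(dec$rho))
  # ordering invariant
  expect_true(all(diff(dec$rho) <= 1e-12))
  expect_error(project_src(dec, st, eeg_recording(eeg$data[1:5, ], 30)),
               "channel count")
})

test_that("rho is invariant to positive rescaling of stimulus or channels", {
  s <- generate_stimulus(60, 30, seed = 4)
  gt <- quiet_truth(n_channels = 8, n_components = 1)
  gt$noise_sd <- 3
  eeg <- generate_eeg(s, gt, "a", seed = 5)
  E <- temporal_embed(stimulus_feature(s, 30)$values, 30)
  dec <- suppressWarnings(fit_cca(E, eeg, 6))
  eeg2 <- eeg
  eeg2$data <- eeg2$data * 3.7
  dec2 <- suppressWarnings(fit_cca(E * 2.2, eeg2, 6))
  expect_equal(dec$rho, dec2$rho, tolerance = 1e-9)
})

test_that("pooling duplicates trials without changing filters and pads boundaries", {
  s <- generate_stimulus(30, 30, seed = 6)
  gt <- quiet_truth(n_channels = 8, n_components = 1)
  gt$noise_sd <- 4
  tr <- list(stimulus = stimulus_feature(s, 30),
             eeg = generate_eeg(s, gt, "a", seed = 7), condition = "a")
  d1 <- pool_and_fit(list(trials = list(tr)), k_components = 6)
  d2 <- pool_and_fit(list(trials = list(tr, tr)), k_components = 6)
  expect_equal(d1$temporal_filters, d2$temporal_filters, tolerance = 1e-8)
  expect_equal(d1$rho, d2$rho, tolerance = 1e-9)
  # lag rows restart with zero padding at the trial boundary
  pooled <- srcflow:::concat_trials(list(tr, tr), 30)
  n <- length(s)
  expect_equal(pooled$S_emb[n + 1, 2:30], rep(0, 29))
  expect_equal(pooled$boundaries, c(n, 2 * n))
  expect_error(pool_and_fit(list(trials = list(
    tr, list(stimulus = tr$stimulus,
             eeg = eeg_recording(tr$eeg$data, 25), condition = "a")))),
    "rates")
})

test_that("stimulus-independent EEG stays at chance level", {
  s <- generate_stimulus(176, 30, seed = 8)
  gt <- quiet_truth(n_channels = 16, n_components = 1)
  gt$noise_sd <- 10
  eeg <- generate_eeg(s, gt, "a", seed = 9)
  set.seed(10)
  eeg$data <- eeg$data[, sample(ncol(eeg$data))]  # break the coupling
  E <- temporal_embed(stimulus_feature(s, 30)$values, 30)
  dec <- suppressWarnings(fit_cca(E, eeg, 11))
  # circular-shift null for the total SRC
  null_tot <- vapply(1:20, function(k) {
    sh <- (seq_len(ncol(eeg$data)) + 97 * k - 1) %% ncol(eeg$data) + 1
    e2 <- eeg
    e2$data <- e2$data[, sh]
    sum(suppressWarnings(fit_cca(E, e2, 11))$rho)
  }, numeric(1))
  expect_lt(sum(dec$rho), quantile(null_tot, 0.95) * 1.5)
  expect_lt(dec$rho[1], 0.3)
})

test_that("a single planted component is recovered at low SNR", {
  # rho1 around 0.3: coefficient-space recovery of the temporal filter
  hc <- vapply(1:5, function(sd2) {
    gt <- generate_ground_truth(n_channels = 96, n_components = 1, seed = sd2,
                                noise_sd = 90, artifact_rate = 0,
                                blink_rate = 0, alpha_amplitude = c(a = 0),
                                condition_gains = c(a = 1))
    trials <- make_trials(gt, 6, duration_s = 176, seed0 = 100 * sd2)
    dec <- suppressWarnings(pool_and_fit(list(trials = trials),
                                         stim_shrinkage = 0.05))
    abs(cor(dec$temporal_filters[, 1], gt$true_temporal_filters[, 1]))
  }, numeric(1))
  expect_gte(median(hc), 0.9)
})

test_that("per-condition SRC table distinguishes planted gains per subject", {
  coh <- generate_cohort(n_subjects = 3,
                         conditions = data.frame(label = c("e", "p"),
                                                 gain = c(1.25, 1),
                                                 alpha_amplitude = c(0, 0)),
                         trials_per_condition = 2, seed = 12, duration_s = 60,
                         n_channels = 48, noise_sd = 15,
                         artifact_rate = 0, blink_rate = 0)
  st <- suppressWarnings(src_table(coh))
  expect_equal(nrow(st), 6)
  expect_setequal(names(st)[1:3], c("subject", "condition", "total_src"))
  expect_equal(st$total_src, rowSums(st[, grep("^rho_", names(st))]),
               tolerance = 1e-12)
  wide <- reshape(st[, 1:3], idvar = "subject", timevar = "condition",
                  direction = "wide")
  expect_gt(mean(wide$total_src.e > wide$total_src.p), 0.5)
})
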