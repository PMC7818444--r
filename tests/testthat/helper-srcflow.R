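# Shared helpers for the srcflow test suite.

# ground truth with all nuisance sources switched off (pure evoked model)
quiet_truth <- function(n_channels = 16, n_components = 1, n_lags = 30,
                        seed = 1, gains = c(a = 1), ...) {
  generate_ground_truth(
    n_channels = n_channels, n_components = n_components, n_lags = n_lags,
    seed = seed, condition_gains = gains,
    alpha_amplitude = stats::setNames(rep(0, length(gains)), names(gains)),
    noise_sd = 0, artifact_rate = 0, blink_rate = 0, ...
  )
}

# one-to-one greedy matching of estimated to true filter columns by |cor|
greedy_match_cor <- function(H_est, H_true) {
  C <- abs(stats::cor(H_est, H_true))
  out <- numeric(ncol(H_true))
  for (k in seq_len(ncol(H_true))) {
    i <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[i[2]] <- C[i[1], i[2]]
    C[i[1], ] <- -1
    C[, i[2]] <- -1
  }
  out
}

# simulated single-condition trial list for one subject
make_trials <- function(truth, n_trials, duration_s = 120, fs = 30,
                        seed0 = 1, condition = "a") {
  lapply(seq_len(n_trials), function(r) {
    s <- generate_stimulus(duration_s, fs, seed = seed0 + 7 * r)
    list(stimulus = stimulus_feature(s, fs),
         eeg = generate_eeg(s, truth, condition, seed = seed0 + 1000 + 13 * r, fs = fs),
         condition = condition)
  })
}

# fraction of periodogram power above a split frequency
power_ratio_above <- function(x, fs, split_hz) {
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  f <- sp$freq * fs
  sum(sp$spec[f >= split_hz]) / sum(sp$spec[f < split_hz])
}
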