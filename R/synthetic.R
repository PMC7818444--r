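# Synthetic-data generators: stimulus, ground-truth response structure, and
# simulated multi-subject EEG with the statistical structure the SRC analysis
# assumes. Every downstream stage of the package can be validated against
# these known ground truths.

#' Generate a slowly varying nonnegative stimulus feature
#'
#' Emulates the optic-flow magnitude of video gameplay: low-pass filtered
#' Gaussian noise, squared so that the series is nonnegative and skewed.
#' The white noise is low-passed at `cutoff_hz / 2` before squaring, so the
#' squared series remains band-limited below `cutoff_hz`.
#'
#' @param duration_s duration in seconds (default 176 s, a typical race trial).
#' @param fs sampling rate in Hz (default 30, the analysis rate).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param cutoff_hz band limit of the feature in Hz (default 3).
#' @return numeric vector of length `round(duration_s * fs)`, nonnegative.
#' @export
generate_stimulus <- function(duration_s = 176, fs = 30, seed = 1, cutoff_hz = 3) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(cutoff_hz, "cutoff_hz")
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist rate", call. = FALSE)
  n <- round(duration_s * fs)
  pad <- max(64L, round(4 * fs / cutoff_hz))
  with_seed(seed, {
    w <- stats::rnorm(n + 2L * pad)
    b <- signal::butter(6, (cutoff_hz / 2) / (fs / 2), type = "low")
    x <- signal::filtfilt(b, w)
    x <- x[(pad + 1L):(pad + n)]
    x^2
  })
}

#' Generate ground-truth response structure for simulation
#'
#' Defines the generative counterpart of the CCA decomposition: per-component
#' temporal filters (unit norm, smooth bumps with configurable peak lags;
#' default peaks at lags 6 and 12, i.e. 200 and 400 ms at 30 Hz) and smooth,
#' linearly independent spatial maps with decreasing strength across
#' components. Also carries the condition-dependent response gains, the
#' condition-dependent alpha (10 Hz) amplitude on designated central channels,
#' the channel noise level, and artifact/blink rates.
#'
#' @param n_channels number of channels D (default 96).
#' @param n_components number of planted components K (default 3).
#' @param n_lags temporal filter length L in samples (default 30).
#' @param seed integer RNG seed.
#' @param peak_lags optional integer vector of filter peak lags (0-based);
#'   default `6, 12, 18, ...` capped below `n_lags`.
#' @param condition_gains named numeric vector of multiplicative response
#'   gains per condition (all > 0).
#' @param alpha_amplitude named numeric vector, 10 Hz amplitude in microvolts
#'   per condition, applied on the central channels.
#' @param component_strengths numeric vector of spatial-map norms in
#'   microvolts, one per component (default `30 / sqrt(1:K)`, a decreasing
#'   strength profile).
#' @param noise_sd channel noise standard deviation in microvolts.
#' @param artifact_rate expected sparse high-amplitude artifacts per minute.
#' @param blink_rate expected ocular blink events per minute.
#' @param blink_amplitude peak blink amplitude in microvolts (frontal channels).
#' @return an object of class `ground_truth`.
#' @export
generate_ground_truth <- function(n_channels = 96, n_components = 3,
                                  n_lags = 30, seed = 1, peak_lags = NULL,
                                  condition_gains = c(active = 1.25,
                                                      sham = 1.25,
                                                      passive = 1.0),
                                  alpha_amplitude = c(active = 1,
                                                      sham = 1,
                                                      passive = 2),
                                  component_strengths = NULL,
                                  noise_sd = 10, artifact_rate = 2,
                                  blink_rate = 12, blink_amplitude = 100) {
  if (n_components > min(n_channels, n_lags)) {
    stop("n_components must not exceed min(n_channels, n_lags)", call. = FALSE)
  }
  if (any(condition_gains <= 0)) stop("all condition gains must be > 0", call. = FALSE)
  if (is.null(peak_lags)) {
    peak_lags <- pmin(6 + 6 * (seq_len(n_components) - 1L), n_lags - 3L)
  }
  if (length(peak_lags) != n_components) {
    stop("peak_lags must have one entry per component", call. = FALSE)
  }

  tau <- seq_len(n_lags) - 1L
  H <- matrix(0, n_lags, n_components)
  for (j in seq_len(n_components)) {
    width <- 2 + 0.5 * (j - 1)
    h <- exp(-(tau - peak_lags[j])^2 / (2 * width^2))
    if (j > 1) {
      # later components get a small early negative lobe (biphasic shape)
      h <- h - 0.35 * exp(-(tau - max(peak_lags[j] - 5, 1))^2 / (2 * width^2))
    }
    i <- which.max(abs(h))
    if (h[i] < 0) h <- -h
    H[, j] <- h / sqrt(sum(h^2))
  }

  maps <- with_seed(seed, {
    repeat {
      A <- matrix(0, n_channels, n_components)
      centers <- round(seq(0.25, 0.75, length.out = n_components) * n_channels)
      idx <- seq_len(n_channels)
      for (j in seq_len(n_components)) {
        bump <- exp(-(idx - centers[j])^2 / (2 * (n_channels / 10)^2))
        rough <- stats::rnorm(n_channels)
        k <- max(3L, round(n_channels / 16))
        sm <- stats::filter(c(rough[1:k], rough, rough[(n_channels - k + 1):n_channels]),
                            rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
        sm <- as.numeric(sm[(k + 1):(k + n_channels)])
        sm[is.na(sm)] <- 0
        a <- bump + 0.8 * sm / max(stats::sd(sm), 1e-12)
        A[, j] <- a / sqrt(sum(a^2))
      }
      if (qr(A)$rank == n_components) break
    }
    if (is.null(component_strengths)) {
      component_strengths <- 30 / sqrt(seq_len(n_components))
    }
    stopifnot(length(component_strengths) == n_components)
    sweep(A, 2, component_strengths, `*`)
  })

  central <- seq(round(0.40 * n_channels), length.out = max(4L, round(n_channels / 12)))
  central <- central[central <= n_channels]
  frontal <- seq_len(min(8L, n_channels))

  structure(
    list(true_temporal_filters = H, true_spatial_maps = maps,
         condition_gains = condition_gains, alpha_amplitude = alpha_amplitude,
         noise_sd = noise_sd, artifact_rate = artifact_rate,
         blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         central_channels = central, frontal_channels = frontal,
         n_lags = n_lags, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d components, %d channels, %d lags\n",
              ncol(x$true_temporal_filters), nrow(x$true_spatial_maps), x$n_lags))
  cat("  gains:", paste(sprintf("%s=%g", names(x$condition_gains),
                                x$condition_gains), collapse = ", "), "\n")
  invisible(x)
}

# 200 ms biphasic blink template at rate fs
blink_template <- function(fs) {
  n <- max(4L, round(0.2 * fs))
  t <- seq(0, 1, length.out = n)
  sin(2 * pi * t) * exp(-((t - 0.35) / 0.45)^2)
}

#' Simulate an EEG trial evoked by a stimulus feature
#'
#' The evoked part is the sum over components of the ground-truth spatial map
#' times the causally filtered stimulus, scaled by the condition gain:
#' `gain * sum_j a_j (h_j * s)(t)`. Added on top: spatially correlated
#' 1/f-shaped noise, a condition-dependent 10 Hz sinusoid on the central
#' channels (random phase per channel), sparse high-amplitude spikes, and a
#' blink-like biphasic ocular transient projected onto the frontal channels.
#'
#' @param stimulus raw (not necessarily z-scored) feature series at the
#'   analysis rate; it is z-scored before convolution.
#' @param truth a `ground_truth` object.
#' @param condition condition label, must be a name of `truth$condition_gains`.
#' @param seed integer RNG seed.
#' @param fs sampling rate in Hz (default 30).
#' @return an `eeg_recording`; the injected blink time course is attached as
#'   attribute `"blink_timecourse"`.
#' @export
generate_eeg <- function(stimulus, truth, condition, seed = 1, fs = 30) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!condition %in% names(truth$condition_gains)) {
    stop(sprintf("unknown condition label '%s'", condition), call. = FALSE)
  }
  s <- as.numeric(stimulus)
  n <- length(s)
  D <- nrow(truth$true_spatial_maps)
  K <- ncol(truth$true_spatial_maps)
  gain <- truth$condition_gains[[condition]]
  s_z <- zscore(s)

  U <- vapply(seq_len(K),
              function(j) conv_causal(s_z, truth$true_temporal_filters[, j]),
              numeric(n))
  X <- gain * (truth$true_spatial_maps %*% t(U))

  blink_tc <- numeric(n)
  with_seed(seed, {
    if (truth$noise_sd > 0) {
      E <- matrix(stats::rnorm(D * n), D, n)
      # temporal colouring: AR(1) gives an approximately 1/f spectrum
      E <- t(apply(E, 1, function(e) as.numeric(stats::filter(e, 0.9, method = "recursive"))))
      # short-range spatial correlation across the channel index
      idx <- seq_len(D)
      Ks <- exp(-outer(idx, idx, function(a, b) (a - b)^2) / (2 * 2^2))
      Ks <- Ks / sqrt(rowSums(Ks^2))
      E <- Ks %*% E
      E <- E / apply(E, 1, stats::sd) * truth$noise_sd
      X <- X + E
    }
    amp <- truth$alpha_amplitude[[condition]]
    if (!is.null(amp) && amp > 0) {
      tt <- (seq_len(n) - 1) / fs
      for (c in truth$central_channels) {
        X[c, ] <- X[c, ] + amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
      }
    }
    if (truth$artifact_rate > 0) {
      n_art <- stats::rpois(1, truth$artifact_rate * n / fs / 60)
      if (n_art > 0) {
        for (k in seq_len(n_art)) {
          ch <- sample.int(D, 1)
          t0 <- sample.int(n, 1)
          X[ch, t0] <- X[ch, t0] + sample(c(-1, 1), 1) * stats::runif(1, 150, 400)
        }
      }
    }
    if (truth$blink_rate > 0 && truth$blink_amplitude > 0) {
      nf <- length(truth$frontal_channels)
      # vertical ocular source: blink train plus slow drift, decaying
      # monotonically over the frontal channels
      tmpl <- blink_template(fs)
      n_blink <- stats::rpois(1, truth$blink_rate * n / fs / 60)
      if (n_blink > 0) {
        starts <- sort(sample.int(n - length(tmpl), n_blink))
        for (t0 in starts) {
          ii <- t0:(t0 + length(tmpl) - 1L)
          blink_tc[ii] <- blink_tc[ii] + tmpl
        }
      }
      # lateral frontal channels (first half) carry the horizontal/gaze
      # source; superior frontal channels (second half) carry the vertical
      # blink source, mirroring horizontal vs vertical EOG derivations
      b_oc <- signal::butter(4, min(4 / (fs / 2), 0.9), type = "low")
      v_drift <- signal::filtfilt(b_oc, stats::rnorm(n))
      v_drift <- v_drift / stats::sd(v_drift)
      v_oc <- truth$blink_amplitude * blink_tc +
        (truth$blink_amplitude / 30) * v_drift
      h_drift <- signal::filtfilt(b_oc, stats::rnorm(n))
      h_drift <- h_drift / stats::sd(h_drift)
      lat <- truth$frontal_channels[seq_len(floor(nf / 2))]
      sup <- setdiff(truth$frontal_channels, lat)
      w_v <- numeric(D)
      w_v[sup] <- seq(1, 0.7, length.out = length(sup))
      w_v[lat] <- 0.25            # blink spill onto the lateral sites
      w_h <- numeric(D)
      w_h[lat] <- c(1, -0.8, 0.7, -0.6)[seq_along(lat)]
      X <- X + outer(w_v, v_oc) +
        (truth$blink_amplitude / 4) * outer(w_h, h_drift)
    }
  })

  out <- eeg_recording(X, rate = fs)
  attr(out, "blink_timecourse") <- blink_tc
  out
}

#' Simulate a multi-subject cohort of SRC sessions
#'
#' Subjects share the ground-truth temporal filter shapes but receive
#' subject-specific perturbations of the spatial maps (additive noise of
#' relative standard deviation `subject_map_sd`, then renormalised to the
#' original map norms) and independent noise realisations. Each condition is
#' repeated `trials_per_condition` times per subject, mirroring a design
#' where every condition of a task is presented twice.
#'
#' @param n_subjects number of subjects (>= 2; default 18).
#' @param conditions data frame with columns `label`, `gain`,
#'   `alpha_amplitude`; defaults to engaged-play conditions with gain 1.25
#'   versus passive viewing with gain 1 and doubled alpha amplitude.
#' @param trials_per_condition trials per condition per subject (default 2).
#' @param seed master integer seed; the whole cohort is reproducible from it.
#' @param duration_s trial duration in seconds (default 176).
#' @param fs analysis sampling rate (default 30 Hz).
#' @param n_channels,n_components,n_lags dimensions of the ground truth.
#' @param noise_sd,artifact_rate,blink_rate,blink_amplitude noise parameters
#'   passed to [generate_ground_truth()].
#' @param subject_map_sd relative SD of per-subject spatial-map perturbations.
#' @return a list of `simulated_session` objects, one per subject, each with
#'   elements `subject`, `trials` (list of `list(stimulus, eeg, condition)`),
#'   and `ground_truth`.
#' @export
generate_cohort <- function(n_subjects = 18,
                            conditions = data.frame(
                              label = c("active", "sham", "passive"),
                              gain = c(1.25, 1.25, 1.0),
                              alpha_amplitude = c(1, 1, 2)),
                            trials_per_condition = 2, seed = 1,
                            duration_s = 176, fs = 30,
                            n_channels = 96, n_components = 3, n_lags = 30,
                            noise_sd = 10, artifact_rate = 2,
                            blink_rate = 12, blink_amplitude = 100,
                            subject_map_sd = 0.2) {
  if (n_subjects < 2) stop("need at least two subjects", call. = FALSE)
  if (nrow(conditions) < 1) stop("condition list must not be empty", call. = FALSE)
  gains <- stats::setNames(conditions$gain, conditions$label)
  alphas <- stats::setNames(conditions$alpha_amplitude, conditions$label)

  base <- generate_ground_truth(
    n_channels = n_channels, n_components = n_components, n_lags = n_lags,
    seed = seed, condition_gains = gains, alpha_amplitude = alphas,
    noise_sd = noise_sd, artifact_rate = artifact_rate,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude
  )
  seeds <- derive_seeds(seed, n_subjects * (1 + 2 * nrow(conditions) * trials_per_condition))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  lapply(seq_len(n_subjects), function(i) {
    truth_i <- base
    truth_i$true_spatial_maps <- with_seed(next_seed(), {
      A <- base$true_spatial_maps
      norms <- sqrt(colSums(A^2))
      P <- A + matrix(stats::rnorm(length(A)), nrow(A)) *
        rep(subject_map_sd * norms / sqrt(nrow(A)), each = nrow(A))
      sweep(P, 2, norms / sqrt(colSums(P^2)), `*`)
    })
    trials <- list()
    for (cond in conditions$label) {
      for (r in seq_len(trials_per_condition)) {
        s_raw <- generate_stimulus(duration_s, fs, seed = next_seed())
        eeg <- generate_eeg(s_raw, truth_i, cond, seed = next_seed(), fs = fs)
        trials[[length(trials) + 1L]] <- list(
          stimulus = stimulus_feature(s_raw, fs, "synthetic"),
          eeg = eeg, condition = cond
        )
      }
    }
    structure(list(subject = i, trials = trials, ground_truth = truth_i),
              class = "simulated_session")
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session> subject %s: %d trials (%s)\n",
              x$subject, length(x$trials),
              paste(unique(vapply(x$trials, `[[`, "", "condition")), collapse = ", ")))
  invisible(x)
}

#' Generate a horizontally translating textured frame sequence
#'
#' A smooth random texture is translated horizontally by `speed` pixels per
#' frame with periodic wrap-around (implemented exactly in the Fourier
#' domain), providing a known-displacement fixture for optic-flow validation.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames (>= 2).
#' @param speed horizontal displacement in px/frame (>= 0, may be fractional).
#' @param seed integer RNG seed.
#' @param smoothness Gaussian blur sigma (px) applied to the base texture.
#' @return a `frame_sequence` at 60 fps.
#' @export
generate_translating_frames <- function(height = 64, width = 64, n_frames = 60,
                                        speed = 1, seed = 1, smoothness = 3) {
  if (speed < 0) stop("speed must be >= 0", call. = FALSE)
  if (n_frames < 2) stop("need at least two frames", call. = FALSE)
  tex <- with_seed(seed, matrix(stats::rnorm(height * width), height, width))
  # periodic Gaussian blur via the 2-D FFT
  gy <- stats::dnorm(pmin(0:(height - 1), height - (0:(height - 1))), sd = smoothness)
  gx <- stats::dnorm(pmin(0:(width - 1), width - (0:(width - 1))), sd = smoothness)
  G <- outer(gy, gx)
  G <- G / sum(G)
  tex <- Re(stats::fft(stats::fft(tex) * stats::fft(G), inverse = TRUE)) /
    (height * width)
  # 0-255 intensity scale, so gradient magnitudes suit the usual
  # smoothness defaults of Horn-Schunck implementations
  tex <- 255 * (tex - min(tex)) / (max(tex) - min(tex))

  # horizontal shifts via the Fourier shift theorem (exact periodic wrap)
  kx <- 0:(width - 1)
  kx[kx > width / 2] <- kx[kx > width / 2] - width
  Ftex <- stats::mvfft(t(tex))  # columns of t(tex) run along width
  frames <- array(0, c(n_frames, height, width))
  for (k in seq_len(n_frames)) {
    ph <- exp(-2i * pi * kx * speed * (k - 1) / width)
    frames[k, , ] <- t(Re(stats::mvfft(Ftex * ph, inverse = TRUE)) / width)
  }
  frame_sequence(frames, 60)
}
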