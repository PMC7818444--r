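# EEG preprocessing: resampling to the analysis rate, zero-phase high-pass
# filtering, robust-PCA denoising, ocular regression via virtual frontal
# electrodes, and iterative channel/sample rejection.

#' Resample EEG to the analysis rate and high-pass filter
#'
#' Applies an anti-alias low-pass at 0.9 x (target Nyquist) with a zero-phase
#' Butterworth cascade, interpolates onto the target sample grid, then
#' high-passes at `hp_cutoff` with a zero-phase 4th-order Butterworth
#' (forward-backward, so temporal response functions are not phase-shifted).
#'
#' @param raw an [eeg_recording()] at the acquisition rate.
#' @param target_rate analysis rate in Hz (default 30; half of a 60 Hz video
#'   frame rate, per Nyquist).
#' @param hp_cutoff high-pass cutoff in Hz (default 1, removing slow drifts).
#' @return an [eeg_recording()] at `target_rate` with fresh validity masks.
#' @export
resample_and_highpass <- function(raw, target_rate = 30, hp_cutoff = 1) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (target_rate >= raw$rate) stop("target_rate must be below the input rate", call. = FALSE)
  if (hp_cutoff <= 0 || hp_cutoff >= target_rate / 2) {
    stop("hp_cutoff must lie in (0, target_rate/2)", call. = FALSE)
  }
  n_in <- ncol(raw$data)
  n_out <- round(n_in * target_rate / raw$rate)
  t_in <- (seq_len(n_in) - 1) / raw$rate
  t_out <- (seq_len(n_out) - 1) / target_rate

  # two cascaded order-4 sections are numerically safer than one order-8
  # transfer function at very low normalised cutoffs (e.g. 500 -> 30 Hz)
  b_aa <- signal::butter(4, 0.9 * (target_rate / 2) / (raw$rate / 2), type = "low")
  b_hp <- signal::butter(4, hp_cutoff / (target_rate / 2), type = "high")
  out <- t(apply(raw$data, 1, function(x) {
    x <- x - mean(x)  # remove DC ahead of filtering (limits edge transients)
    y <- signal::filtfilt(b_aa, signal::filtfilt(b_aa, x))
    y <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
    signal::filtfilt(b_hp, y)
  }))
  eeg_recording(out, rate = target_rate, channel_labels = raw$channel_labels)
}

#' Robust PCA by principal component pursuit
#'
#' Decomposes a data matrix into a low-rank part `L` and a sparse part `S`
#' (`data = L + S`) with the inexact augmented-Lagrange-multiplier algorithm.
#' Sparse, high-amplitude entries (artifacts, which volume conduction cannot
#' produce as genuinely sparse brain activity) are captured in `S`, and the
#' low-rank part replaces the data downstream. The effective sparsity weight
#' is `lam / sqrt(max(dim(data)))`, following the convention of the
#' augmented-Lagrangian reference implementations, so `lam = 1` is the
#' classical principal-component-pursuit choice and the default here is 0.5.
#'
#' @param data numeric channels x samples matrix, all finite.
#' @param lam sparsity weight (> 0, default 0.5).
#' @param tol convergence tolerance on `||data - L - S||_F / ||data||_F`
#'   (default 1e-7).
#' @param max_iter maximum number of iterations (default 500); on
#'   non-convergence the best iterate is returned with a warning.
#' @return list with elements `L` (low-rank), `S` (sparse), `iterations`,
#'   `converged`.
#' @export
robust_pca <- function(data, lam = 0.5, tol = 1e-7, max_iter = 500) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("robust_pca requires finite input", call. = FALSE)
  assert_scalar_pos(lam, "lam")
  lambda <- lam / sqrt(max(dim(data)))
  normF <- function(m) sqrt(sum(m^2))
  soft <- function(m, tau) sign(m) * pmax(abs(m) - tau, 0)

  d_norm <- normF(data)
  if (d_norm == 0) {
    return(list(L = data, S = data * 0, iterations = 0L, converged = TRUE))
  }
  sv <- svd(data, nu = 0, nv = 0)$d
  norm2 <- sv[1]
  norm_inf <- max(abs(data)) / lambda
  Y <- data / max(norm2, norm_inf)
  mu <- 1.25 / norm2
  mu_bar <- mu * 1e7
  rho <- 1.5
  L <- matrix(0, nrow(data), ncol(data))
  S <- L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    S <- soft(data - L + Y / mu, lambda / mu)
    dec <- svd(data - S + Y / mu)
    dsh <- pmax(dec$d - 1 / mu, 0)
    r <- sum(dsh > 0)
    L <- if (r > 0) {
      dec$u[, seq_len(r), drop = FALSE] %*%
        (dsh[seq_len(r)] * t(dec$v[, seq_len(r), drop = FALSE]))
    } else {
      L * 0
    }
    Z <- data - L - S
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
    if (normF(Z) / d_norm < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("robust_pca did not converge; returning best iterate", call. = FALSE)
  }
  list(L = L, S = S, iterations = it, converged = converged)
}

#' Build virtual ocular electrodes from frontal channels
#'
#' Each of the four virtual electrodes is a signed sum of frontal channel
#' time series, chosen to capture blink (vertical, summed superior-frontal
#' channels) and saccade (horizontal, lateral-frontal differences)
#' topographies. The default construction uses the eight frontal-most
#' channels: two lateral difference pairs and two superior sums.
#'
#' @param eeg an [eeg_recording()].
#' @param frontal_sets list of 4 "construction" lists; each element is a list
#'   of `(channel index, +/- 1)` pairs, e.g. `list(list(1, +1), list(2, -1))`.
#'   Defaults to the eight frontal-most channels as described above.
#' @return object of class `ocular_regressors`: `signals` (4 x T matrix) and
#'   `construction`.
#' @export
build_ocular_regressors <- function(eeg, frontal_sets = NULL) {
  stopifnot(inherits(eeg, "eeg_recording"))
  D <- nrow(eeg$data)
  if (is.null(frontal_sets)) {
    if (D < 8) stop("default ocular construction needs >= 8 channels", call. = FALSE)
    frontal_sets <- list(
      list(list(1L, +1), list(2L, -1)),   # horizontal, left pair
      list(list(3L, +1), list(4L, -1)),   # horizontal, right pair
      list(list(5L, +1), list(6L, +1)),   # vertical blink proxy
      list(list(7L, +1), list(8L, +1))    # vertical blink proxy
    )
  }
  if (length(frontal_sets) != 4L) {
    stop("exactly four virtual electrodes are required", call. = FALSE)
  }
  sig <- matrix(0, 4L, ncol(eeg$data))
  for (r in seq_len(4L)) {
    for (term in frontal_sets[[r]]) {
      ch <- term[[1]]
      sgn <- term[[2]]
      if (ch < 1 || ch > D) stop("ocular term references a missing channel", call. = FALSE)
      if (!eeg$valid_channels[ch]) {
        stop(sprintf("ocular term references rejected channel %d", ch), call. = FALSE)
      }
      sig[r, ] <- sig[r, ] + sgn * eeg$data[ch, ]
    }
  }
  structure(list(signals = sig, construction = frontal_sets),
            class = "ocular_regressors")
}

#' Regress ocular activity out of every EEG channel
#'
#' Each channel is replaced by its least-squares residual after projection
#' onto the span of the four virtual ocular electrodes (plus an intercept).
#' Linearly dependent regressors are dropped with a warning.
#'
#' @param eeg an [eeg_recording()].
#' @param regressors an `ocular_regressors` object from
#'   [build_ocular_regressors()].
#' @return the cleaned [eeg_recording()].
#' @export
regress_out <- function(eeg, regressors) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(regressors, "ocular_regressors"))
  if (ncol(regressors$signals) != ncol(eeg$data)) {
    stop("regressor and EEG lengths differ", call. = FALSE)
  }
  X <- cbind(1, t(regressors$signals))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("dropping linearly dependent ocular regressors", call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(eeg$data)))
  out <- eeg
  out$data <- resid
  out
}

#' Iterative rejection of outlier channels and samples
#'
#' Per iteration: (a) channels whose mean power exceeds the mean of the
#' currently valid channel powers by `n_sd` standard deviations are marked
#' invalid; (b) within each valid channel, samples whose absolute amplitude
#' exceeds the channel's mean absolute amplitude by `n_sd` standard
#' deviations are marked invalid together with their immediate neighbours.
#' Statistics are recomputed from the surviving entries at every iteration.
#' Invalid samples are zeroed in the data and flagged in `valid_samples`, so
#' downstream covariance estimation can exclude them; masks only ever shrink.
#'
#' @param eeg an [eeg_recording()].
#' @param n_sd rejection threshold in standard deviations (default 4).
#' @param n_iter number of iterations (default 3).
#' @return the masked [eeg_recording()].
#' @export
iterative_rejection <- function(eeg, n_sd = 4, n_iter = 3) {
  stopifnot(inherits(eeg, "eeg_recording"))
  assert_scalar_pos(n_sd, "n_sd")
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  X <- eeg$data
  vc <- eeg$valid_channels
  vs <- eeg$valid_samples
  n <- ncol(X)
  for (it in seq_len(n_iter)) {
    live <- which(vc)
    if (length(live) == 0L) stop("all channels rejected", call. = FALSE)
    pow <- vapply(live, function(i) {
      v <- vs[i, ]
      if (!any(v)) return(NA_real_)
      mean(X[i, v]^2)
    }, numeric(1))
    thr <- mean(pow, na.rm = TRUE) + n_sd * stats::sd(pow, na.rm = TRUE)
    if (is.finite(thr)) {
      bad <- live[!is.na(pow) & pow > thr]
      vc[bad] <- FALSE
      vs[bad, ] <- FALSE
      X[bad, ] <- 0
    }
    for (i in which(vc)) {
      v <- vs[i, ]
      if (sum(v) < 3L) next
      a <- abs(X[i, v])
      s_thr <- mean(a) + n_sd * stats::sd(a)
      bad_t <- which(v)[abs(X[i, v]) > s_thr]
      if (length(bad_t)) {
        bad_t <- unique(pmin(pmax(c(bad_t - 1L, bad_t, bad_t + 1L), 1L), n))
        vs[i, bad_t] <- FALSE
        X[i, bad_t] <- 0
      }
    }
  }
  if (!any(vc)) stop("all channels rejected", call. = FALSE)
  out <- eeg
  out$data <- X
  out$valid_channels <- vc
  out$valid_samples <- vs
  out
}

#' Full EEG preprocessing chain
#'
#' Applies, in order: resampling + high-pass ([resample_and_highpass()],
#' skipped when the data are already at the target rate), robust PCA keeping
#' the low-rank part ([robust_pca()]), ocular regression
#' ([build_ocular_regressors()] + [regress_out()]), and iterative rejection
#' ([iterative_rejection()]). A per-stage log is attached as attribute
#' `"log"`.
#'
#' @param raw an [eeg_recording()].
#' @param target_rate analysis rate in Hz (default 30).
#' @param hp_cutoff high-pass cutoff in Hz (default 1).
#' @param rpca_lambda robust-PCA sparsity weight (default 0.5); `NULL` skips
#'   the stage.
#' @param frontal_sets ocular construction passed to
#'   [build_ocular_regressors()]; `NULL` uses the default, `NA` skips the
#'   stage.
#' @param n_sd,n_iter rejection parameters (defaults 4 and 3).
#' @return the preprocessed [eeg_recording()] with attribute `"log"`.
#' @export
preprocess_eeg <- function(raw, target_rate = 30, hp_cutoff = 1,
                           rpca_lambda = 0.5, frontal_sets = NULL,
                           n_sd = 4, n_iter = 3) {
  stopifnot(inherits(raw, "eeg_recording"))
  log <- list()
  x <- raw
  if (raw$rate > target_rate) {
    x <- resample_and_highpass(raw, target_rate, hp_cutoff)
    log$resample <- sprintf("resampled %g -> %g Hz, high-pass %g Hz",
                            raw$rate, target_rate, hp_cutoff)
  } else {
    b_hp <- signal::butter(4, hp_cutoff / (x$rate / 2), type = "high")
    x$data <- t(apply(x$data, 1, function(ch) signal::filtfilt(b_hp, ch)))
    log$resample <- sprintf("already at %g Hz; high-pass %g Hz only",
                            x$rate, hp_cutoff)
  }
  if (!is.null(rpca_lambda)) {
    rp <- robust_pca(x$data, lam = rpca_lambda)
    x$data <- rp$L
    log$robust_pca <- sprintf(
      "robust PCA: %d iterations, sparse fraction %.3f%%",
      rp$iterations, 100 * mean(rp$S != 0))
  }
  if (!(length(frontal_sets) == 1L && is.na(frontal_sets[[1]][1]))) {
    oc <- build_ocular_regressors(x, frontal_sets)
    x <- regress_out(x, oc)
    log$ocular <- "regressed out 4 virtual ocular electrodes"
  }
  n_ch_before <- sum(x$valid_channels)
  x <- iterative_rejection(x, n_sd = n_sd, n_iter = n_iter)
  log$rejection <- sprintf(
    "rejection: %d channel(s) removed, %.2f%% of samples masked",
    n_ch_before - sum(x$valid_channels), 100 * (1 - mean(x$valid_samples)))
  attr(x, "log") <- log
  x
}
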