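# Stimulus feature extraction from video: luminance conversion and
# area-average downsampling, Horn-Schunck dense optic flow, per-frame scalar
# features (mean flow magnitude, temporal contrast), and resampling of the
# feature series to the EEG analysis rate with z-scoring.

# Area-averaging resize matrix mapping n_in samples onto n_out bins.
# Entry [i, j] is the fraction of output bin i covered by input pixel j.
resize_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) M[i, j] <- overlap / scale
    }
  }
  M
}

#' Convert raw video frames to an analysis-ready grayscale sequence
#'
#' Colour frames are converted to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), then resized by area averaging to the
#' target resolution (default 320 x 180).
#'
#' @param raw_frames numeric array: `T x H x W x 3` (colour) or `T x H x W`
#'   (already grayscale). Intensities may be 0-1 or 0-255; they are passed
#'   through unchanged.
#' @param target_h,target_w output height and width in pixels.
#' @param frame_rate frames per second of the input (default 60).
#' @return a [frame_sequence()].
#' @export
preprocess_frames <- function(raw_frames, target_h = 180, target_w = 320,
                              frame_rate = 60) {
  d <- dim(raw_frames)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("raw_frames must be a T x H x W (x 3) array", call. = FALSE)
  }
  if (target_h < 2 || target_w < 2) stop("target size must be >= 2x2", call. = FALSE)
  n <- d[1]; h <- d[2]; w <- d[3]
  if (length(d) == 4L) {
    if (d[4] != 3L) stop("colour frames must have 3 channels", call. = FALSE)
    gray <- 0.299 * raw_frames[, , , 1] + 0.587 * raw_frames[, , , 2] +
      0.114 * raw_frames[, , , 3]
  } else {
    gray <- raw_frames
  }
  Rh <- resize_matrix(h, target_h)
  Rw <- resize_matrix(w, target_w)
  out <- array(0, c(n, target_h, target_w))
  for (k in seq_len(n)) {
    out[k, , ] <- Rh %*% gray[k, , ] %*% t(Rw)
  }
  frame_sequence(out, frame_rate)
}

# shift a matrix by (dy, dx) with edge replication
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Horn-Schunck dense optic flow
#'
#' Estimates a dense displacement field for every consecutive frame pair
#' using the classic global (smoothness-regularised) formulation: spatial and
#' temporal gradients from 2x2x2 finite-difference stencils over the frame
#' pair, followed by `n_iter` Jacobi updates from zero initialisation using
#' the local-average form of the Euler-Lagrange equations,
#' `u = ubar - Ex (Ex ubar + Ey vbar + Et) / (alpha^2 + Ex^2 + Ey^2)`.
#'
#' @param frames a [frame_sequence()] with at least two frames.
#' @param smoothness regularisation weight alpha (> 0, default 1).
#' @param n_iter number of Jacobi iterations (default 10).
#' @return a [flow_field()] with `u_x`, `u_y` in px/frame.
#' @export
horn_schunck_flow <- function(frames, smoothness = 1, n_iter = 10) {
  stopifnot(inherits(frames, "frame_sequence"))
  assert_scalar_pos(smoothness, "smoothness")
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  d <- dim(frames$frames)
  n <- d[1]
  if (n < 2) stop("need at least two frames for optic flow", call. = FALSE)
  h <- d[2]; w <- d[3]
  a2 <- smoothness^2

  # weighted 8-neighbour averaging kernel of the original formulation
  avg <- function(m) {
    (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
       shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
      (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
         shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
  }

  ux <- array(0, c(n - 1L, h, w))
  uy <- array(0, c(n - 1L, h, w))
  for (k in seq_len(n - 1L)) {
    I1 <- frames$frames[k, , ]
    I2 <- frames$frames[k + 1L, , ]
    # 2x2x2 cube stencils; x runs along columns, y along rows
    Ex <- (shift_mat(I1, 0, 1) - I1 + shift_mat(I1, 1, 1) - shift_mat(I1, 1, 0) +
             shift_mat(I2, 0, 1) - I2 + shift_mat(I2, 1, 1) - shift_mat(I2, 1, 0)) / 4
    Ey <- (shift_mat(I1, 1, 0) - I1 + shift_mat(I1, 1, 1) - shift_mat(I1, 0, 1) +
             shift_mat(I2, 1, 0) - I2 + shift_mat(I2, 1, 1) - shift_mat(I2, 0, 1)) / 4
    Et <- (I2 - I1 + shift_mat(I2, 1, 0) - shift_mat(I1, 1, 0) +
             shift_mat(I2, 0, 1) - shift_mat(I1, 0, 1) +
             shift_mat(I2, 1, 1) - shift_mat(I1, 1, 1)) / 4
    denom <- a2 + Ex^2 + Ey^2
    u <- matrix(0, h, w)
    v <- matrix(0, h, w)
    for (it in seq_len(n_iter)) {
      ub <- avg(u)
      vb <- avg(v)
      common <- (Ex * ub + Ey * vb + Et) / denom
      u <- ub - Ex * common
      v <- vb - Ey * common
    }
    ux[k, , ] <- u
    uy[k, , ] <- v
  }
  flow_field(ux, uy)
}

#' Scalar per-frame feature from a frame sequence
#'
#' `optic_flow`: mean over pixels of the flow magnitude
#' `sqrt(u_x^2 + u_y^2)` for each frame pair. `temporal_contrast`: mean over
#' pixels of the (by default absolute) frame-to-frame intensity difference.
#'
#' @param frames a [frame_sequence()].
#' @param flow a [flow_field()]; required for `optic_flow`.
#' @param feature_name `"optic_flow"` or `"temporal_contrast"`.
#' @param rectify take the absolute frame difference before averaging
#'   (default TRUE); a signed mean would largely cancel on pan-dominated
#'   content.
#' @return numeric vector of length `T - 1`.
#' @export
frame_feature <- function(frames, flow = NULL,
                          feature_name = c("optic_flow", "temporal_contrast"),
                          rectify = TRUE) {
  feature_name <- match.arg(feature_name)
  stopifnot(inherits(frames, "frame_sequence"))
  if (feature_name == "optic_flow") {
    if (is.null(flow)) stop("optic_flow requires a flow field", call. = FALSE)
    mag <- sqrt(flow$u_x^2 + flow$u_y^2)
    apply(mag, 1, mean)
  } else {
    n <- dim(frames$frames)[1]
    dif <- frames$frames[2:n, , , drop = FALSE] -
      frames$frames[1:(n - 1), , , drop = FALSE]
    if (rectify) dif <- abs(dif)
    apply(dif, 1, mean)
  }
}

#' Resample a per-frame feature series to the EEG analysis rate
#'
#' When the frame rate is an integer multiple of the EEG rate the series is
#' anti-aliased by averaging consecutive frame groups (60 to 30 Hz: mean of
#' adjacent pairs); otherwise it is low-pass filtered and interpolated onto
#' the target grid. The result is z-scored.
#'
#' @param series numeric per-frame feature values.
#' @param frame_rate rate of `series` in Hz.
#' @param eeg_rate target analysis rate in Hz (default 30).
#' @param feature_name label stored on the result.
#' @return a [stimulus_feature()] (z-scored).
#' @export
feature_to_eeg_rate <- function(series, frame_rate, eeg_rate = 30,
                                feature_name = "optic_flow") {
  if (frame_rate < eeg_rate) stop("frame_rate must be >= eeg_rate", call. = FALSE)
  series <- as.numeric(series)
  if (frame_rate %% eeg_rate == 0) {
    f <- frame_rate / eeg_rate
    n_out <- floor(length(series) / f)
    if (n_out < 1) stop("series too short to resample", call. = FALSE)
    idx <- matrix(seq_len(n_out * f), nrow = f)
    out <- colMeans(matrix(series[idx], nrow = f))
  } else {
    b <- signal::butter(6, 0.9 * (eeg_rate / 2) / (frame_rate / 2), type = "low")
    y <- signal::filtfilt(b, series)
    t_in <- (seq_along(series) - 1) / frame_rate
    n_out <- floor(length(series) * eeg_rate / frame_rate)
    t_out <- (seq_len(n_out) - 1) / eeg_rate
    out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  }
  stimulus_feature(out, eeg_rate, feature_name, zscore = TRUE)
}
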