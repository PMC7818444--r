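# Lightweight S3 containers used throughout the package.

#' EEG recording container
#'
#' A multichannel EEG segment: a channels-by-samples matrix in microvolts,
#' its sampling rate, channel labels, and validity masks filled in by the
#' artifact-rejection stage. Invalid samples are zeroed in `data` and
#' excluded from covariance estimation via `valid_samples`.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param rate sampling rate in Hz.
#' @param channel_labels optional character vector of channel names.
#' @param valid_channels optional logical vector, one entry per channel.
#' @param valid_samples optional logical matrix matching `dim(data)`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels = NULL,
                          valid_channels = NULL, valid_samples = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("EEG data must be a finite numeric matrix", call. = FALSE)
  }
  assert_scalar_pos(rate, "rate")
  d <- nrow(data)
  n <- ncol(data)
  if (d < 1L || n < 1L) stop("EEG data must have >= 1 channel and sample", call. = FALSE)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%03d", seq_len(d))
  if (length(channel_labels) != d) stop("channel_labels length mismatch", call. = FALSE)
  if (is.null(valid_channels)) valid_channels <- rep(TRUE, d)
  if (is.null(valid_samples)) valid_samples <- matrix(TRUE, d, n)
  if (length(valid_channels) != d || !identical(dim(valid_samples), dim(data))) {
    stop("validity masks must match the data dimensions", call. = FALSE)
  }
  structure(
    list(data = data, rate = rate, channel_labels = channel_labels,
         valid_channels = valid_channels, valid_samples = valid_samples),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat(sprintf("  valid channels: %d/%d; valid samples: %.1f%%\n",
              sum(x$valid_channels), length(x$valid_channels),
              100 * mean(x$valid_samples)))
  invisible(x)
}

#' Scalar stimulus feature time series
#'
#' A z-scored scalar feature s(t) at the analysis rate, e.g. mean optic-flow
#' magnitude or temporal contrast of a video.
#'
#' @param values numeric vector (will be z-scored unless already).
#' @param rate sampling rate in Hz.
#' @param feature_name one of `"optic_flow"`, `"temporal_contrast"`,
#'   `"synthetic"`.
#' @param zscore logical; z-score `values` (default TRUE).
#' @return an object of class `stimulus_feature`.
#' @export
stimulus_feature <- function(values, rate,
                             feature_name = c("synthetic", "optic_flow",
                                              "temporal_contrast"),
                             zscore = TRUE) {
  feature_name <- match.arg(feature_name)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("feature values must be finite", call. = FALSE)
  assert_scalar_pos(rate, "rate")
  if (zscore && length(values) > 1L) values <- zscore(values)
  structure(list(values = values, rate = rate, feature_name = feature_name),
            class = "stimulus_feature")
}

#' @export
print.stimulus_feature <- function(x, ...) {
  cat(sprintf("<stimulus_feature> %s: %d samples @ %g Hz\n",
              x$feature_name, length(x$values), x$rate))
  invisible(x)
}

#' Grayscale frame sequence
#'
#' @param frames numeric array, frames x height x width, finite intensities.
#' @param frame_rate frames per second.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate) {
  if (length(dim(frames)) != 3L) stop("frames must be a T x H x W array", call. = FALSE)
  if (dim(frames)[1] < 2L) stop("need at least two frames", call. = FALSE)
  if (any(!is.finite(frames))) stop("frame intensities must be finite", call. = FALSE)
  assert_scalar_pos(frame_rate, "frame_rate")
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %dx%d @ %g fps\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Dense optic-flow field
#'
#' Per-pixel displacements (px/frame) for each consecutive frame pair.
#'
#' @param u_x,u_y numeric arrays, (T-1) x H x W.
#' @return an object of class `flow_field`.
#' @export
flow_field <- function(u_x, u_y) {
  if (!identical(dim(u_x), dim(u_y)) || length(dim(u_x)) != 3L) {
    stop("u_x and u_y must be (T-1) x H x W arrays of equal shape", call. = FALSE)
  }
  if (any(!is.finite(u_x)) || any(!is.finite(u_y))) {
    stop("flow values must be finite", call. = FALSE)
  }
  structure(list(u_x = u_x, u_y = u_y), class = "flow_field")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> K=%d components, L=%d lags, D=%d channels\n",
              x$K, x$n_lags, nrow(x$spatial_filters)))
  cat("  rho:", paste(sprintf("%.3f", x$rho), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.src_result <- function(x, ...) {
  cat(sprintf("<src_result> total SRC = %.4f over %d components (%s, n=%d samples)\n",
              x$total_src, length(x$per_component),
              if (is.null(x$condition)) "unlabelled" else x$condition,
              x$n_samples_used))
  invisible(x)
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation_test_result> %d entries, %d permutations, q=%g\n",
              length(x$p_values), x$n_perm, x$q))
  cat(sprintf("  significant entries: %d (min p = %.4g)\n",
              sum(x$significant), min(x$p_values)))
  invisible(x)
}
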