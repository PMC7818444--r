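# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are deterministic without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a vector of child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# z-score a vector; errors on zero variance (degenerate input fails loudly).
zscore <- function(x, tol = .Machine$double.eps^0.5) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    stop("cannot z-score a (near-)constant series", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Causal FIR convolution y(t) = sum_k h[k] x(t - k + 1), zero-padded at the
# start so that length(y) == length(x).
conv_causal <- function(x, h) {
  n <- length(x)
  L <- length(h)
  y <- stats::filter(c(rep(0, L - 1L), x), h, method = "convolution", sides = 1L)
  as.numeric(y[L:(n + L - 1L)])
}

# Mean power (over a mask) of the part of a periodogram within [lo, hi) Hz.
band_power_ratio <- function(x, fs, split_hz) {
  sp <- stats::spec.pgram(x, taper = 0, plot = FALSE, detrend = TRUE)
  f <- sp$freq * fs
  hi <- sum(sp$spec[f >= split_hz])
  lo <- sum(sp$spec[f < split_hz])
  hi / lo
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
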