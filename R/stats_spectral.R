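# Alpha-band power maps and the nonparametric statistical battery: paired
# Wilcoxon signed-rank tests, rank-sum subgroup tests, subject-label-swap
# permutation tests, and Benjamini-Hochberg FDR control over electrodes or
# lags.

#' Per-channel alpha-band power
#'
#' Band-passes every channel with a zero-phase Butterworth filter (default
#' 8-12 Hz, 4th order) and returns the temporal mean square of the filter
#' output over the channel's valid samples, in microvolts squared.
#'
#' @param eeg an [eeg_recording()].
#' @param band numeric length-2 band edges in Hz (default `c(8, 12)`).
#' @param order Butterworth order (default 4).
#' @return object of class `alpha_power_map`: numeric vector `power`
#'   (length D, `NA` for rejected channels), plus `band`.
#' @export
alpha_power <- function(eeg, band = c(8, 12), order = 4) {
  stopifnot(inherits(eeg, "eeg_recording"))
  nyq <- eeg$rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  b <- signal::butter(order, band / nyq, type = "pass")
  D <- nrow(eeg$data)
  pow <- rep(NA_real_, D)
  for (i in seq_len(D)) {
    if (!eeg$valid_channels[i]) next
    x <- eeg$data[i, ]
    if (all(x == 0)) {
      pow[i] <- 0
      next
    }
    y <- signal::filtfilt(b, x)
    v <- eeg$valid_samples[i, ]
    pow[i] <- mean(y[v]^2)
  }
  structure(list(power = pow, band = band), class = "alpha_power_map")
}

#' Per-subject, per-condition alpha power for a cohort
#'
#' Computes [alpha_power()] per trial and averages across each subject's
#' trials within a condition (power is averaged across repeated trials
#' before any statistical test).
#'
#' @param cohort list of sessions (e.g. from [generate_cohort()]).
#' @param band,order passed to [alpha_power()].
#' @return named list of subjects x channels matrices, one per condition.
#' @export
alpha_power_table <- function(cohort, band = c(8, 12), order = 4) {
  if (!is.null(cohort$trials)) cohort <- list(cohort)
  conds <- unique(unlist(lapply(cohort, function(ss)
    vapply(ss$trials, `[[`, "", "condition"))))
  out <- list()
  for (cond in conds) {
    rows <- lapply(cohort, function(ss) {
      sel <- ss$trials[vapply(ss$trials, function(tr) tr$condition == cond, logical(1))]
      pw <- vapply(sel, function(tr) alpha_power(tr$eeg, band, order)$power,
                   numeric(nrow(sel[[1]]$eeg$data)))
      rowMeans(pw)
    })
    out[[cond]] <- do.call(rbind, rows)
  }
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences with zero-difference exclusion and
#' mid-ranks for ties. The p-value is exact (by enumeration over sign
#' patterns) for n <= 25 without ties, and uses the normal approximation
#' with tie and continuity corrections otherwise. The z statistic from the
#' normal approximation is always reported.
#'
#' @param x,y paired numeric vectors of equal length (n >= 5 after removing
#'   zero differences).
#' @param alternative `"two.sided"` (default), `"greater"` (x > y), or
#'   `"less"`.
#' @return list with `statistic` (V, the positive-rank sum), `z`, `p`,
#'   `n` (pairs used), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; test undefined", call. = FALSE)
  if (n < 5) warning("fewer than 5 nonzero differences", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))

  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  cc <- switch(alternative,
               two.sided = sign(V - mu) * 0.5,
               greater = 0.5,
               less = -0.5)
  z <- (V - mu - cc) / sqrt(sig2)

  if (n <= 25) {
    # exact null distribution of V by enumeration over the 2^n sign
    # patterns, computed as a polynomial convolution over the (doubled,
    # hence integer even with mid-ranks) rank values
    r2 <- round(2 * r)
    counts <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):length(probs)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    exact <- TRUE
  } else {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    exact <- FALSE
  }
  list(statistic = V, z = z, p = p, n = n, exact = exact)
}

#' Wilcoxon rank-sum (Mann-Whitney) test for two independent groups
#'
#' Exact p-value for small tie-free samples, normal approximation with
#' continuity correction otherwise (delegating the p-value computation to
#' [stats::wilcox.test()]); additionally reports the normal-approximation z.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger), `"less"`.
#' @return list with `statistic` (Mann-Whitney U of `x`), `z`, `p`, `exact`.
#' @export
rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = !ties, correct = TRUE))
  n1 <- length(x); n2 <- length(y)
  U <- unname(wt$statistic)
  r <- rank(c(x, y))
  tie_tab <- table(r)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                            sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(statistic = U, z = z, p = wt$p.value, exact = !ties && (n1 * n2 < 10000))
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure: flags every p-value at or below the largest `p_(k)`
#' with `p_(k) <= k q / m`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return logical mask, `TRUE` for discoveries.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Paired-map permutation test with FDR control
#'
#' Tests a per-entry condition difference of paired subject maps (one map
#' per subject per condition: electrodes or lags). The observed statistic is
#' the group-mean difference. The null distribution is built by randomly
#' swapping each subject's pair of condition labels (a sign flip of that
#' subject's difference) with probability 1/2, independently per subject and
#' permutation. Two-sided p-values use the `(1 + #exceedances)/(n_perm + 1)`
#' convention (so p >= 1/(n_perm+1)), and Benjamini-Hochberg FDR is applied
#' across entries.
#'
#' @param maps_a,maps_b numeric subjects x entries matrices, paired by row.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param q FDR level (default 0.05).
#' @param seed integer RNG seed (results are deterministic given the seed).
#' @return object of class `permutation_test_result` with `observed`,
#'   `null` (n_perm x entries), `p_values`, `significant`, `n_perm`, `q`.
#' @export
permutation_condition_test <- function(maps_a, maps_b, n_perm = 1000,
                                       q = 0.05, seed = 1) {
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (!identical(dim(maps_a), dim(maps_b))) {
    stop("paired maps must have identical shape", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  d <- maps_a - maps_b
  n <- nrow(d)
  observed <- colMeans(d)
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    (signs %*% d) / n
  })
  exceed <- colSums(abs(null) >= matrix(abs(observed), n_perm,
                                        length(observed), byrow = TRUE))
  p <- (1 + exceed) / (n_perm + 1)
  structure(
    list(observed = observed, null = null, p_values = p,
         significant = fdr_bh(p, q), n_perm = n_perm, q = q),
    class = "permutation_test_result"
  )
}

#' Channel-wise paired contrast of alpha power maps
#'
#' Per-channel paired two-tailed Wilcoxon signed-rank tests across subjects
#' with Benjamini-Hochberg correction over channels (the default path for
#' alpha maps), or the subject-permutation machinery.
#'
#' @param maps_a,maps_b subjects x channels matrices, paired by row.
#' @param method `"wilcoxon"` (default) or `"permutation"`.
#' @param q FDR level (default 0.05).
#' @param n_perm,seed used by the permutation path.
#' @return list with `difference` (group-mean a - b), `p_values`,
#'   `significant`.
#' @export
alpha_condition_contrast <- function(maps_a, maps_b,
                                     method = c("wilcoxon", "permutation"),
                                     q = 0.05, n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (method == "wilcoxon") {
    p <- vapply(seq_len(ncol(maps_a)), function(j) {
      wilcoxon_signed_rank(maps_a[, j], maps_b[, j])$p
    }, numeric(1))
    list(difference = colMeans(maps_a - maps_b), p_values = p,
         significant = fdr_bh(p, q))
  } else {
    pt <- permutation_condition_test(maps_a, maps_b, n_perm = n_perm,
                                     q = q, seed = seed)
    list(difference = pt$observed, p_values = pt$p_values,
         significant = pt$significant)
  }
}
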