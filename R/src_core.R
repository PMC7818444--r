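# Core stimulus-response correlation computation: temporal embedding of the
# stimulus, canonical correlation analysis between the lag matrix and the
# EEG with the EEG covariance truncated to its leading eigenvalues, total
# SRC, and projection of held-out data through fitted filters.

#' Temporal lag embedding of a stimulus feature
#'
#' Builds the T x L matrix whose row t is `[s(t), s(t-1), ..., s(t-L+1)]`
#' with zero padding for indices before the start of the series. Only causal
#' lags are used: the EEG response lags the stimulus.
#'
#' @param s a [stimulus_feature()] or numeric vector.
#' @param n_lags number of lags L (>= 1; the series must be at least that
#'   long).
#' @return numeric matrix, `length(s) x n_lags`.
#' @export
temporal_embed <- function(s, n_lags) {
  x <- if (inherits(s, "stimulus_feature")) s$values else as.numeric(s)
  n <- length(x)
  if (n_lags < 1) stop("n_lags must be >= 1", call. = FALSE)
  if (n < n_lags) stop("series shorter than the number of lags", call. = FALSE)
  E <- matrix(0, n, n_lags)
  for (l in seq_len(n_lags)) {
    E[l:n, l] <- x[1:(n - l + 1L)]
  }
  E
}

# Pairwise-deletion covariance of the rows of X under a logical validity
# mask V (same shape). Entry (i, j) uses only samples valid in both rows.
masked_cov <- function(X, V) {
  Vn <- V * 1
  Xz <- X * Vn
  n_ij <- Vn %*% t(Vn)
  n_ij[n_ij < 2] <- NA
  Sxy <- Xz %*% t(Xz)
  A <- Xz %*% t(Vn)     # A[i, j] = sum of x_i over samples valid in j
  C <- (Sxy - A * t(A) / n_ij) / n_ij
  C[!is.finite(C)] <- 0
  C
}

# Cross-covariance between rows of X (mask V) and rows of Y (assumed fully
# valid): entry (i, k) uses the samples valid in row i of X.
masked_cross_cov <- function(X, V, Y) {
  Vn <- V * 1
  Xz <- X * Vn
  n_i <- rowSums(Vn)
  Sxy <- Xz %*% t(Y)
  mx <- rowSums(Xz) / n_i
  my <- (Vn %*% t(Y)) / n_i
  (Sxy - n_i * mx * my) / n_i
}

#' Fit the stimulus-response CCA
#'
#' Solves for pairs of temporal (stimulus-side) and spatial (EEG-side)
#' filters whose outputs are maximally correlated. The EEG covariance is
#' eigendecomposed and the data projected onto the leading `k_components`
#' eigenvectors (or the smallest number explaining `var_frac` of the
#' variance), which regularises the EEG side by truncating its eigenvalue
#' spectrum. Standard CCA is then solved by SVD of the whitened
#' cross-covariance, spatial filters are mapped back to channel space, and
#' forward models are computed as `a_j = C_rr w_j / (w_j' C_rr w_j)`.
#' Components are ordered by decreasing correlation, with signs fixed so the
#' largest-magnitude temporal-filter coefficient is positive.
#'
#' Samples flagged invalid in the recording's mask are excluded from all
#' covariance estimates by pairwise deletion.
#'
#' @param S_emb lag matrix from [temporal_embed()], T x L.
#' @param eeg an [eeg_recording()] with T samples.
#' @param k_components EEG-dimensionality truncation K (default 11); must
#'   not exceed `min(L, D)`. Ignored when `var_frac` is given.
#' @param var_frac optional variance fraction in (0, 1]; keeps the smallest
#'   number of eigenvectors whose eigenvalues sum to at least this fraction.
#' @param stim_rank_tol relative eigenvalue tolerance defining the numerical
#'   rank of the lag-embedded stimulus (default 1e-5). Band-limited stimuli
#'   yield lag covariances whose trailing eigenvalues sit at the filter
#'   stopband floor; whitening those directions only amplifies noise in the
#'   temporal filters, so they are dropped (with a warning when the
#'   reduction is substantial). Broadband stimuli are unaffected.
#' @param stim_shrinkage optional ridge shrinkage of the stimulus-side
#'   whitening, expressed as a fraction of the mean lag-covariance
#'   eigenvalue (default 0: exact CCA). For strongly autocorrelated
#'   stimuli the inverse-square-root whitening amplifies sampling noise in
#'   weak eigendirections by `1/sqrt(lambda)`; a small shrinkage (0.05 is a
#'   robust choice, the result is flat over 0.05-0.2) stabilises the
#'   coefficient-space shape of the temporal filters at a negligible cost
#'   in canonical correlation. Leave at 0 when exact canonical correlations
#'   are required.
#' @return an object of class `component_decomposition` with elements
#'   `rho`, `temporal_filters` (L x K), `spatial_filters` (D x K),
#'   `forward_models` (D x K), `u`, `v` (T x K component time courses),
#'   `pca_basis`, `K`, `n_lags`, `n_samples_used`.
#' @export
fit_cca <- function(S_emb, eeg, k_components = 11, var_frac = NULL,
                    stim_rank_tol = 1e-5, stim_shrinkage = 0) {
  stopifnot(inherits(eeg, "eeg_recording"))
  S_emb <- as.matrix(S_emb)
  L <- ncol(S_emb)
  D <- nrow(eeg$data)
  n <- ncol(eeg$data)
  if (nrow(S_emb) != n) stop("stimulus and EEG sample counts differ", call. = FALSE)

  live <- which(eeg$valid_channels)
  X <- eeg$data[live, , drop = FALSE]
  V <- eeg$valid_samples[live, , drop = FALSE]
  D_eff <- length(live)

  C_rr <- masked_cov(X, V)
  C_rs <- masked_cross_cov(X, V, t(S_emb))       # D_eff x L
  C_ss <- stats::cov(S_emb) * (n - 1) / n

  er <- eigen(C_rr, symmetric = TRUE)
  ev <- pmax(er$values, 0)
  if (!is.null(var_frac)) {
    stopifnot(var_frac > 0, var_frac <= 1)
    K <- which(cumsum(ev) / sum(ev) >= var_frac)[1]
  } else {
    K <- k_components
  }
  if (K > D_eff) {
    stop("k_components must not exceed the number of valid channels", call. = FALSE)
  }
  tol_r <- max(ev) * 1e-12
  K <- min(K, sum(ev > tol_r))
  W_r <- er$vectors[, seq_len(K), drop = FALSE] %*%
    diag(1 / sqrt(ev[seq_len(K)]), K)

  es <- eigen(C_ss, symmetric = TRUE)
  evs <- pmax(es$values, 0)
  L_eff <- sum(evs > max(evs) * stim_rank_tol)
  if (L_eff < L / 2) {
    warning(sprintf("rank-deficient stimulus embedding; using %d of %d lag dimensions",
                    L_eff, L), call. = FALSE)
  }
  gamma <- stim_shrinkage * mean(evs)
  W_s <- es$vectors[, seq_len(L_eff), drop = FALSE] %*%
    diag(1 / sqrt(evs[seq_len(L_eff)] + gamma), L_eff)

  n_valid <- sum(V) / D_eff
  if (n_valid < 10 * (L + K)) {
    warning("fewer valid samples than 10 x (n_lags + K); estimates may be unstable",
            call. = FALSE)
  }

  M <- t(W_s) %*% t(C_rs) %*% W_r               # L_eff x K
  sv <- svd(M)
  n_comp <- min(K, L_eff)
  rho <- pmin(sv$d[seq_len(n_comp)], 1)
  H <- W_s %*% sv$u[, seq_len(n_comp), drop = FALSE]
  Wmat <- W_r %*% sv$v[, seq_len(n_comp), drop = FALSE]

  # forward models in the full channel space (zeros on rejected channels)
  quad <- colSums(Wmat * (C_rr %*% Wmat))
  A_eff <- sweep(C_rr %*% Wmat, 2, quad, `/`)
  W_full <- matrix(0, D, n_comp)
  A_full <- matrix(0, D, n_comp)
  W_full[live, ] <- Wmat
  A_full[live, ] <- A_eff

  # sign convention: largest-magnitude temporal coefficient positive
  for (j in seq_len(n_comp)) {
    if (H[which.max(abs(H[, j])), j] < 0) {
      H[, j] <- -H[, j]
      W_full[, j] <- -W_full[, j]
      A_full[, j] <- -A_full[, j]
    }
  }

  Xc <- X - rowMeans(X)
  u <- sweep(S_emb, 2, colMeans(S_emb)) %*% H
  v <- t(Xc) %*% W_full[live, , drop = FALSE]

  structure(
    list(rho = rho, temporal_filters = H, spatial_filters = W_full,
         forward_models = A_full, u = u, v = v,
         pca_basis = list(vectors = er$vectors[, seq_len(K), drop = FALSE],
                          values = ev[seq_len(K)]),
         K = n_comp, n_lags = L, valid_channels = eeg$valid_channels,
         n_samples_used = round(n_valid)),
    class = "component_decomposition"
  )
}

#' Total stimulus-response correlation
#'
#' Sums the per-component canonical correlations into the single dependent
#' measure of evoked-response strength.
#'
#' @param decomp a `component_decomposition`, an `src_result`, or a numeric
#'   vector of per-component correlations.
#' @param condition,subject optional labels stored on the result.
#' @return an object of class `src_result`.
#' @export
total_src <- function(decomp, condition = NULL, subject = NULL) {
  rho <- if (inherits(decomp, "component_decomposition")) {
    decomp$rho
  } else if (inherits(decomp, "src_result")) {
    decomp$per_component
  } else {
    as.numeric(decomp)
  }
  if (length(rho) < 1) stop("need at least one component", call. = FALSE)
  n_used <- if (inherits(decomp, "component_decomposition")) decomp$n_samples_used
            else if (inherits(decomp, "src_result")) decomp$n_samples_used
            else NA_integer_
  structure(list(total_src = sum(rho), per_component = rho,
                 condition = condition, subject = subject,
                 n_samples_used = n_used),
            class = "src_result")
}

#' Project data through fitted CCA filters
#'
#' Applies the fitted temporal filters to a (new) stimulus and the fitted
#' spatial filters to (new) EEG, computes per-component Pearson correlations
#' over the jointly valid samples, and sums them. No refitting takes place,
#' so SRCs for different conditions are measured over a common basis.
#'
#' @param decomp a fitted `component_decomposition`.
#' @param s a [stimulus_feature()] or numeric vector at the analysis rate.
#' @param eeg an [eeg_recording()] with the same channel count as the fit.
#' @param condition,subject optional labels stored on the result.
#' @return an `src_result`.
#' @export
project_src <- function(decomp, s, eeg, condition = NULL, subject = NULL) {
  stopifnot(inherits(decomp, "component_decomposition"),
            inherits(eeg, "eeg_recording"))
  if (nrow(eeg$data) != nrow(decomp$spatial_filters)) {
    stop("channel count differs from the fitted decomposition", call. = FALSE)
  }
  S_emb <- temporal_embed(s, decomp$n_lags)
  if (nrow(S_emb) != ncol(eeg$data)) {
    stop("stimulus and EEG sample counts differ", call. = FALSE)
  }
  u <- S_emb %*% decomp$temporal_filters
  v <- t(eeg$data) %*% decomp$spatial_filters
  ok <- apply(eeg$valid_samples[eeg$valid_channels, , drop = FALSE], 2, all)
  if (sum(ok) < 3) stop("too few jointly valid samples", call. = FALSE)
  rho <- vapply(seq_len(decomp$K),
                function(j) stats::cor(u[ok, j], v[ok, j]),
                numeric(1))
  total_src(rho, condition = condition, subject = subject) ->
    out
  out$n_samples_used <- sum(ok)
  out
}

#' Pool trials and fit a common CCA basis
#'
#' Concatenates the valid samples of the selected trials (per subject across
#' conditions by default, or across subjects for group-level components) and
#' fits [fit_cca()] once on the pooled data. The lag embedding restarts with
#' zero padding at every trial boundary, so no lag row mixes samples from
#' different trials.
#'
#' @param sessions a single session (list with a `trials` element, as
#'   produced by [generate_cohort()]) or a list of such sessions.
#' @param pooling `"conditions"` (default): one decomposition per subject,
#'   pooled across that subject's conditions; `"subjects"`: a single
#'   decomposition pooled across all subjects and conditions.
#' @param n_lags lag-embedding length L (default 30; about 0-970 ms at
#'   30 Hz).
#' @param k_components,var_frac passed to [fit_cca()].
#' @return a `component_decomposition` (or a list of them, one per subject,
#'   when `pooling = "conditions"` and several sessions are given).
#' @export
pool_and_fit <- function(sessions, pooling = c("conditions", "subjects"),
                         n_lags = 30, k_components = 11, var_frac = NULL,
                         ...) {
  pooling <- match.arg(pooling)
  if (!is.null(sessions$trials)) sessions <- list(sessions)
  if (length(sessions) < 1) stop("need at least one session", call. = FALSE)

  fit_one <- function(trials) {
    rates <- vapply(trials, function(tr) tr$eeg$rate, numeric(1))
    if (length(unique(rates)) != 1) stop("inconsistent sampling rates", call. = FALSE)
    pooled <- concat_trials(trials, n_lags)
    dec <- fit_cca(pooled$S_emb, pooled$eeg,
                   k_components = k_components, var_frac = var_frac, ...)
    attr(dec, "trial_boundaries") <- pooled$boundaries
    dec
  }

  if (pooling == "subjects") {
    all_trials <- do.call(c, lapply(sessions, `[[`, "trials"))
    fit_one(all_trials)
  } else if (length(sessions) == 1L) {
    fit_one(sessions[[1]]$trials)
  } else {
    lapply(sessions, function(ss) fit_one(ss$trials))
  }
}

# Concatenate trials: lag embedding restarts (zero padding) at every trial
# boundary; channel mask is the intersection across trials.
concat_trials <- function(trials, n_lags) {
  S_emb <- do.call(rbind, lapply(trials, function(tr) temporal_embed(tr$stimulus, n_lags)))
  X <- do.call(cbind, lapply(trials, function(tr) tr$eeg$data))
  V <- do.call(cbind, lapply(trials, function(tr) tr$eeg$valid_samples))
  vc <- Reduce(`&`, lapply(trials, function(tr) tr$eeg$valid_channels))
  eeg <- eeg_recording(X, rate = trials[[1]]$eeg$rate,
                       channel_labels = trials[[1]]$eeg$channel_labels,
                       valid_channels = vc, valid_samples = V)
  list(S_emb = S_emb, eeg = eeg,
       boundaries = cumsum(vapply(trials, function(tr) ncol(tr$eeg$data), numeric(1))))
}

# Project a set of trials through a fitted decomposition, restarting the lag
# embedding at trial boundaries; returns an src_result.
project_trials <- function(decomp, trials, condition = NULL, subject = NULL) {
  pooled <- concat_trials(trials, decomp$n_lags)
  u <- pooled$S_emb %*% decomp$temporal_filters
  v <- t(pooled$eeg$data) %*% decomp$spatial_filters
  live <- pooled$eeg$valid_channels
  ok <- apply(pooled$eeg$valid_samples[live, , drop = FALSE], 2, all)
  rho <- vapply(seq_len(decomp$K),
                function(j) stats::cor(u[ok, j], v[ok, j]), numeric(1))
  out <- total_src(rho, condition = condition, subject = subject)
  out$n_samples_used <- sum(ok)
  out
}

#' Per-condition SRC table for a cohort
#'
#' For every subject, fits a common basis on that subject's pooled trials
#' ([pool_and_fit()]), then projects each condition's concatenated trials
#' through the fitted filters ([project_src()]). This reproduces the
#' "common basis for all conditions" workflow.
#'
#' @param cohort list of sessions from [generate_cohort()] (or of the same
#'   shape).
#' @param k_components,var_frac passed to [fit_cca()].
#' @param n_lags lag-embedding length (default 30).
#' @param average_trials if TRUE, the SRC of a condition is the mean of its
#'   per-trial SRCs instead of the SRC of the concatenated trials.
#' @return data frame with columns `subject`, `condition`, `total_src`, and
#'   `rho_1 ... rho_K`.
#' @export
src_table <- function(cohort, k_components = 11, var_frac = NULL,
                      n_lags = 30, average_trials = FALSE, ...) {
  if (!is.null(cohort$trials)) cohort <- list(cohort)
  rows <- list()
  for (ss in cohort) {
    trials <- ss$trials
    dec <- pool_and_fit(list(list(trials = trials)), pooling = "conditions",
                        n_lags = n_lags, k_components = k_components,
                        var_frac = var_frac, ...)
    conds <- unique(vapply(trials, `[[`, "", "condition"))
    for (cond in conds) {
      sel <- trials[vapply(trials, function(tr) tr$condition == cond, logical(1))]
      if (average_trials) {
        res <- lapply(sel, function(tr) project_trials(dec, list(tr)))
        rho <- rowMeans(vapply(res, `[[`, numeric(dec$K), "per_component"))
        sr <- total_src(rho, condition = cond, subject = ss$subject)
      } else {
        sr <- project_trials(dec, sel, condition = cond, subject = ss$subject)
      }
      row <- data.frame(subject = ss$subject, condition = cond,
                        total_src = sr$total_src)
      for (j in seq_along(sr$per_component)) {
        row[[sprintf("rho_%d", j)]] <- sr$per_component[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  # component count can differ slightly across subjects (stimulus numerical
  # rank); pad missing per-component columns with NA
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  })
  do.call(rbind, rows)
}
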