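# Condition-specific spatial and temporal response functions: regressions of
# pooled-basis stimulus components onto each condition's EEG (spatial), and
# of the stimulus onto spatially filtered condition EEG over lags (temporal).

#' Condition-specific spatial response functions
#'
#' Multivariate least-squares regression (with intercept) of the filtered
#' stimulus components `u_1..u_J` from a pooled-basis fit onto each EEG
#' channel of one condition. The weights are the per-channel strength of
#' the evoked response to each filtered stimulus, in microvolts per unit of
#' filtered (z-scored) stimulus.
#'
#' @param u_components numeric T x J matrix of filtered stimulus components.
#' @param eeg_cond an [eeg_recording()] restricted to one condition, with T
#'   samples.
#' @return numeric J x D weight matrix.
#' @export
spatial_response_by_condition <- function(u_components, eeg_cond) {
  stopifnot(inherits(eeg_cond, "eeg_recording"))
  U <- as.matrix(u_components)
  if (nrow(U) != ncol(eeg_cond$data)) stop("length mismatch", call. = FALSE)
  ok <- apply(eeg_cond$valid_samples[eeg_cond$valid_channels, , drop = FALSE], 2, all)
  X <- cbind(1, U[ok, , drop = FALSE])
  B <- qr.coef(qr(X), t(eeg_cond$data[, ok, drop = FALSE]))
  W <- B[-1, , drop = FALSE]
  rownames(W) <- NULL
  W
}

#' Condition-specific temporal response functions
#'
#' For each spatially filtered response component `v_j` of one condition,
#' least-squares regression (with intercept) of `v_j(t)` on the lag-embedded
#' stimulus. The coefficient series over lags is the temporal response
#' function: the time course of the evoked response relative to stimulus
#' presentation. Unlike a naive cross-correlation, the full least-squares
#' solve deconvolves the stimulus autocorrelation.
#'
#' @param s a [stimulus_feature()] or numeric vector.
#' @param v_components numeric T x J matrix of spatially filtered EEG.
#' @param n_lags lag count L.
#' @return numeric J x L coefficient matrix.
#' @export
temporal_response_by_condition <- function(s, v_components, n_lags) {
  V <- as.matrix(v_components)
  E <- temporal_embed(s, n_lags)
  if (nrow(V) != nrow(E)) stop("length mismatch", call. = FALSE)
  if (nrow(E) < 10 * n_lags) {
    warning("fewer samples than 10 x n_lags; temporal weights may be noisy",
            call. = FALSE)
  }
  X <- cbind(1, E)
  B <- qr.coef(qr(X), V)
  t(B[-1, , drop = FALSE])
}

#' Per-condition response functions for one subject
#'
#' Convenience wrapper reproducing the condition-comparison workflow: the
#' first `n_components` temporal filters of a pooled-basis decomposition are
#' applied to each condition's stimulus, and the corresponding spatial
#' filters to each condition's EEG; condition-specific spatial and temporal
#' response functions are then estimated by regression.
#'
#' @param decomp a pooled-basis `component_decomposition` for this subject.
#' @param session a session (list with `trials`) for the same subject.
#' @param n_components number of components analysed (default 3).
#' @return object of class `response_function_set`: lists `spatial`
#'   (per condition, J x D) and `temporal` (per condition, J x L), plus
#'   `subject`.
#' @export
response_function_set <- function(decomp, session, n_components = 3) {
  stopifnot(inherits(decomp, "component_decomposition"))
  J <- min(n_components, decomp$K)
  trials <- session$trials
  conds <- unique(vapply(trials, `[[`, "", "condition"))
  spatial <- list()
  temporal <- list()
  for (cond in conds) {
    sel <- trials[vapply(trials, function(tr) tr$condition == cond, logical(1))]
    pooled <- concat_trials(sel, decomp$n_lags)
    u <- pooled$S_emb %*% decomp$temporal_filters[, seq_len(J), drop = FALSE]
    spatial[[cond]] <- spatial_response_by_condition(u, pooled$eeg)
    v <- t(pooled$eeg$data) %*% decomp$spatial_filters[, seq_len(J), drop = FALSE]
    stim <- do.call(c, lapply(sel, function(tr) {
      if (inherits(tr$stimulus, "stimulus_feature")) tr$stimulus$values
      else as.numeric(tr$stimulus)
    }))
    temporal[[cond]] <- temporal_response_by_condition(stim, v, decomp$n_lags)
  }
  structure(list(spatial = spatial, temporal = temporal,
                 subject = session$subject),
            class = "response_function_set")
}

#' Group-average response functions
#'
#' Elementwise mean across subjects, per condition, of spatial and temporal
#' response functions.
#'
#' @param sets list of `response_function_set` objects of identical shape.
#' @return a `response_function_set` with `subject = "group-average"`.
#' @export
group_average <- function(sets) {
  if (length(sets) == 0) stop("empty list of response-function sets", call. = FALSE)
  conds <- names(sets[[1]]$spatial)
  avg <- function(field, cond) {
    Reduce(`+`, lapply(sets, function(s) s[[field]][[cond]])) / length(sets)
  }
  structure(
    list(spatial = stats::setNames(lapply(conds, function(cc) avg("spatial", cc)), conds),
         temporal = stats::setNames(lapply(conds, function(cc) avg("temporal", cc)), conds),
         subject = "group-average"),
    class = "response_function_set"
  )
}
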