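# End-to-end orchestration: simulate (or accept) a cohort, preprocess,
# fit the pooled CCA basis per subject, measure per-condition SRC, estimate
# response functions, compute alpha maps, and run the statistical contrasts.

#' Default analysis configuration
#'
#' Collects every tunable constant of the workflow with defaults set to the
#' canonical analysis settings: 30 Hz analysis rate, 1 Hz high-pass, L = 30
#' lags, K = 11 EEG dimensions, robust-PCA weight 0.5, 4-SD rejection over
#' 3 iterations, 8-12 Hz alpha band with a 4th-order filter, 1000
#' permutations, FDR level 0.05.
#'
#' @param ... named overrides of any default, including a nested
#'   `simulation` list passed to [generate_cohort()].
#' @return a named list of class `srcflow_config`.
#' @export
srcflow_config <- function(...) {
  cfg <- list(
    analysis_rate = 30, hp_cutoff = 1,
    n_lags = 30, k_components = 11, var_frac = NULL,
    rpca_lambda = 0.5, reject_n_sd = 4, reject_n_iter = 3,
    alpha_band = c(8, 12), alpha_order = 4,
    n_perm = 1000, q = 0.05,
    n_rf_components = 3,
    preprocess = FALSE,
    seed = 1,
    simulation = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "srcflow_config")
}

#' Run the full stimulus-response correlation pipeline
#'
#' Stages: simulate a cohort (unless one is supplied), optionally preprocess
#' every trial, fit a pooled CCA basis per subject, project each condition
#' to obtain the per-condition SRC table, run paired Wilcoxon contrasts on
#' total SRC, compute per-subject alpha-power maps and their channel-wise
#' contrasts, estimate condition-specific response functions, and test
#' group-level response-function differences between the first two
#' conditions with the subject-permutation machinery.
#'
#' @param config an [srcflow_config()].
#' @param cohort optional pre-built cohort (list of sessions); when `NULL`,
#'   one is generated from `config$simulation` and `config$seed`.
#' @return a list of class `srcflow_run` with elements `config`, `src`
#'   (data frame), `src_contrasts`, `alpha` (per-condition matrices),
#'   `alpha_contrasts`, `response_functions` (group average),
#'   `rf_permutation`, and `log`.
#' @export
run_pipeline <- function(config = srcflow_config(), cohort = NULL) {
  stopifnot(inherits(config, "srcflow_config"))
  log <- list()
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) {
    sim_args <- config$simulation
    sim_args$seed <- config$seed
    cohort <- do.call(generate_cohort, sim_args)
    log$simulate <- sprintf("simulated %d subjects x %d trials",
                            length(cohort), length(cohort[[1]]$trials))
  }
  if (isTRUE(config$preprocess)) {
    cohort <- lapply(cohort, function(ss) {
      ss$trials <- lapply(ss$trials, function(tr) {
        tr$eeg <- preprocess_eeg(tr$eeg, target_rate = config$analysis_rate,
                                 hp_cutoff = config$hp_cutoff,
                                 rpca_lambda = config$rpca_lambda,
                                 n_sd = config$reject_n_sd,
                                 n_iter = config$reject_n_iter)
        tr
      })
      ss
    })
    log$preprocess <- "preprocessed all trials"
  }

  src <- src_table(cohort, k_components = config$k_components,
                   var_frac = config$var_frac, n_lags = config$n_lags)
  log$src <- sprintf("SRC table: %d rows", nrow(src))

  conds <- unique(src$condition)
  totals <- lapply(conds, function(cc) src$total_src[src$condition == cc])
  names(totals) <- conds
  contrasts <- list()
  if (length(conds) >= 2) {
    for (i in seq_len(length(conds) - 1)) {
      for (j in seq((i + 1), length(conds))) {
        key <- sprintf("%s_vs_%s", conds[i], conds[j])
        contrasts[[key]] <- wilcoxon_signed_rank(totals[[i]], totals[[j]])
      }
    }
  }

  alpha <- alpha_power_table(cohort, band = config$alpha_band,
                             order = config$alpha_order)
  alpha_contrasts <- list()
  if (length(conds) >= 2) {
    for (i in seq_len(length(conds) - 1)) {
      for (j in seq((i + 1), length(conds))) {
        key <- sprintf("%s_vs_%s", conds[i], conds[j])
        alpha_contrasts[[key]] <- alpha_condition_contrast(
          alpha[[conds[i]]], alpha[[conds[j]]], q = config$q)
      }
    }
  }

  decs <- pool_and_fit(cohort, pooling = "conditions",
                       n_lags = config$n_lags,
                       k_components = config$k_components,
                       var_frac = config$var_frac)
  if (inherits(decs, "component_decomposition")) decs <- list(decs)
  rf_sets <- mapply(function(dec, ss) {
    response_function_set(dec, ss, n_components = config$n_rf_components)
  }, decs, cohort, SIMPLIFY = FALSE)
  rf_group <- group_average(rf_sets)

  rf_perm <- NULL
  if (length(conds) >= 2) {
    c1 <- conds[1]; c2 <- conds[2]
    sp_a <- t(vapply(rf_sets, function(s) s$spatial[[c1]][1, ],
                     numeric(ncol(rf_sets[[1]]$spatial[[c1]]))))
    sp_b <- t(vapply(rf_sets, function(s) s$spatial[[c2]][1, ],
                     numeric(ncol(rf_sets[[1]]$spatial[[c2]]))))
    rf_perm <- permutation_condition_test(sp_a, sp_b, n_perm = config$n_perm,
                                          q = config$q, seed = config$seed)
    log$rf_perm <- sprintf("spatial RF permutation %s vs %s: %d significant channels",
                           c1, c2, sum(rf_perm$significant))
  }
  log$elapsed_s <- proc.time()[["elapsed"]] - t0

  structure(
    list(config = config, src = src, src_contrasts = contrasts,
         alpha = alpha, alpha_contrasts = alpha_contrasts,
         response_functions = rf_group, rf_permutation = rf_perm,
         log = log),
    class = "srcflow_run"
  )
}

#' @export
print.srcflow_run <- function(x, ...) {
  cat("<srcflow_run>\n")
  cat(sprintf("  SRC rows: %d (%s)\n", nrow(x$src),
              paste(unique(x$src$condition), collapse = ", ")))
  for (nm in names(x$src_contrasts)) {
    ct <- x$src_contrasts[[nm]]
    cat(sprintf("  total SRC %s: z = %.2f, p = %.4g\n", nm, ct$z, ct$p))
  }
  invisible(x)
}
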