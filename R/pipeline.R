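#' End-to-end condition-discrimination analysis on synthetic EEG
#'
#' Runs the full pipeline per simulated participant -- schedule, synthetic
#' epochs (or noise-only resting snippets), preprocessing, single-trial TRF
#' fitting, leave-one-out prediction scoring, correlation indices -- and
#' aggregates to participant-level summaries. Memory stays bounded because
#' each participant's epochs are discarded after scoring.
#'
#' @param spec A [simulation_spec()].
#' @param conditions Named list of [condition_spec()]s, default
#'   [study_conditions()].
#' @param cfg A [ridge_config()].
#' @param seed Integer seed; per-participant streams are derived from it.
#' @param noise_only If `TRUE`, run on condition-free resting noise
#'   (the null control) instead of TRF-driven task epochs.
#' @param gains Ground-truth regressor gains, default [condition_gains()].
#' @param index_on Scale for the inverse-logit of the correlation index,
#'   `"z"` (default) or `"r"`.
#' @param progress Print one line per participant.
#' @return A list of class `pipeline_result`:
#'   \describe{
#'     \item{index}{named list of participants x channels mean-index
#'       matrices, one per testing condition}
#'     \item{contrast}{participants x channels matrix of the index
#'       difference, testing nonpredictive minus strongly predictive}
#'     \item{summary}{per (testing, training) condition: mean r, t-based
#'       95\% CI and n, pooled over participants (one mean z per
#'       participant per cell)}
#'     \item{participant_z}{per participant and condition pair, mean Fisher
#'       z of the prediction correlations}
#'     \item{spec, cfg, seed, noise_only}{inputs, for provenance}
#'   }
#' @export
run_discrimination_pipeline <- function(spec = simulation_spec(),
                                        conditions = study_conditions(),
                                        cfg = ridge_config(),
                                        seed = 1, noise_only = FALSE,
                                        gains = condition_gains(),
                                        index_on = "z",
                                        progress = FALSE) {
  regs <- study_hazard_regressors(conditions, fs = spec$fs,
                                  window = spec$window)
  trfs <- NULL
  if (!noise_only)
    trfs <- lapply(stats::setNames(nm = names(conditions)), function(cnd)
      simulate_ground_truth_trf(spec, cnd, cfg, gains = gains))
  schedule <- simulate_schedule(spec, conditions, seed = seed)
  cond_labels <- sort(unique(schedule$condition))
  n_chan <- spec$n_channels
  chans <- rownames(simulate_layout(n_chan))
  idx_mats <- lapply(stats::setNames(nm = cond_labels), function(...)
    matrix(NA_real_, spec$n_participants, n_chan,
           dimnames = list(NULL, chans)))
  part_z <- vector("list", spec$n_participants)
  for (pp in seq_len(spec$n_participants)) {
    sched_p <- schedule[schedule$participant == pp, , drop = FALSE]
    seed_p <- (seed + 104729L * pp) %% .Machine$integer.max
    ep <- if (noise_only)
      simulate_resting_snippets(sched_p, spec, seed = seed_p)
    else
      simulate_epochs(sched_p, trfs, regs, spec, cfg, seed = seed_p)
    ep <- preprocess_epochs(ep)
    sc <- loo_predict_scores(ep, regs, cfg)
    sc$participant <- pp
    ind <- score_indices(sc, on = index_on)
    for (cnd in cond_labels) {
      m <- index_matrix(ind, testing_condition = cnd)
      idx_mats[[cnd]][pp, colnames(m)] <- m[1, ]
    }
    agg <- stats::aggregate(z ~ testing_condition + training_condition,
                            data = sc[is.finite(sc$z), ], FUN = mean)
    agg$participant <- pp
    part_z[[pp]] <- agg
    if (progress)
      message(sprintf("participant %d/%d done", pp, spec$n_participants))
  }
  part_z <- do.call(rbind, part_z)
  cells <- unique(part_z[, c("testing_condition", "training_condition")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- part_z$testing_condition == cells$testing_condition[i] &
      part_z$training_condition == cells$training_condition[i]
    ci <- correlation_ci(part_z$z[sel])
    data.frame(testing_condition = cells$testing_condition[i],
               training_condition = cells$training_condition[i],
               mean_r = ci$mean_r, ci_lo_r = ci$ci_r[1],
               ci_hi_r = ci$ci_r[2], mean_z = ci$mean_z, n = ci$n)
  }))
  summ <- summ[order(summ$testing_condition, summ$training_condition), ]
  rownames(summ) <- NULL
  contrast <- idx_mats[["nonpredictive"]] - idx_mats[["strongly_predictive"]]
  structure(list(index = idx_mats, contrast = contrast, summary = summ,
                 participant_z = part_z, spec = spec, cfg = cfg,
                 seed = seed, noise_only = noise_only),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$spec$n_participants, " participants, ",
      if (x$noise_only) "noise-only control" else "task simulation",
      ", seed ", x$seed, "\n", sep = "")
  mi <- vapply(x$index, function(m) mean(m, na.rm = TRUE), 0)
  cat("  mean correlation index by testing condition:\n")
  for (nm in names(mi)) cat(sprintf("    %-20s % .4f\n", nm, mi[nm]))
  invisible(x)
}

#' Cluster test on the nonpredictive-vs-strongly-predictive index contrast
#'
#' Convenience wrapper: runs the cluster-based permutation test on the
#' participants x electrodes matrix of index differences (testing
#' nonpredictive minus strongly predictive) from a pipeline result, using
#' the k-nearest-neighbour adjacency of the simulated layout.
#'
#' @param result A `pipeline_result`.
#' @param alpha,n_perm,seed Passed to [cluster_permutation_test()].
#' @param k Neighbours for the adjacency graph, default 4.
#' @return A `cluster_result`.
#' @export
contrast_cluster_test <- function(result, alpha = 0.025, n_perm = 1000,
                                  seed = NULL, k = 4) {
  stopifnot(inherits(result, "pipeline_result"))
  coords <- simulate_layout(result$spec$n_channels)
  adj <- knn_adjacency(coords, k = k, labels = rownames(coords))
  cluster_permutation_test(result$contrast, adj, alpha = alpha,
                           n_perm = n_perm, seed = seed)
}
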