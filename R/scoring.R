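#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)`, variance-stabilising for averaging correlations. Values
#' with `|r| >= 1` are clipped to `+/-(1 - 1e-12)` with a warning.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  bad <- is.finite(r) & abs(r) >= 1
  if (any(bad)) {
    warning("correlations with |r| >= 1 clipped before Fisher z", call. = FALSE)
    r[bad] <- sign(r[bad]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Parametric confidence interval for a mean correlation
#'
#' Computes the t-based confidence interval for the mean of Fisher
#' z-transformed correlations and reports it on both the z and r scales.
#'
#' @param z Numeric vector of Fisher z values (across trials or
#'   participants), `n >= 2`.
#' @param level Confidence level, default 0.95.
#' @return List with `mean_z`, `ci_z` (length 2), `mean_r`, `ci_r`, `n`.
#' @export
correlation_ci <- function(z, level = 0.95) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 2)
    stop("insufficient-data: need at least 2 values for a confidence interval",
         call. = FALSE)
  m <- mean(z)
  se <- stats::sd(z) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  ci <- c(m - q * se, m + q * se)
  list(mean_z = m, ci_z = ci, mean_r = tanh(m), ci_r = tanh(ci), n = n)
}

#' Bounded correlation index contrasting two trained models
#'
#' Maps each model's (Fisher z-transformed) prediction correlation through
#' the inverse logit to a positive scale, then takes the normalised
#' difference `(a - b) / (a + b)`, where `a` comes from the model trained
#' on the nonpredictive condition and `b` from the model trained on the
#' strongly predictive condition. Positive values mean the nonpredictive
#' model fits better, negative the strongly predictive model, 0 a tie. The
#' index is bounded in (-1, 1) for finite inputs.
#'
#' @param z_np,z_sp Correlation values (Fisher z by default) for the
#'   nonpredictive- and strongly-predictive-trained models.
#' @param on Apply the inverse logit to Fisher `"z"` values (default) or to
#'   raw `"r"` correlations (inputs are then tanh-transformed back first).
#' @return Numeric vector of indices.
#' @export
correlation_index <- function(z_np, z_sp, on = c("z", "r")) {
  on <- match.arg(on)
  if (identical(on, "r")) {
    z_np <- tanh(z_np)
    z_sp <- tanh(z_sp)
  }
  a <- stats::plogis(z_np)
  b <- stats::plogis(z_sp)
  (a - b) / (a + b)
}

# Pearson correlations between matching columns of two matrices, over the
# first `k` rows. Returns NA where either column is constant.
col_cors <- function(x, y, k) {
  x <- x[seq_len(k), , drop = FALSE]
  y <- y[seq_len(k), , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  sx <- sqrt(colSums(x^2))
  sy <- sqrt(colSums(y^2))
  r <- colSums(x * y) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

#' Leave-one-out prediction correlations for condition-trained models
#'
#' For each participant, fits one TRF per trial (all conditions jointly
#' lag-expanded in one design), then scores every trial against models
#' trained on each condition: the training TRF is the leave-one-out average
#' over the other trials when training and testing condition coincide, and
#' the all-trials average of the training condition otherwise. Predictions
#' are correlated with the observed trial per channel over the pre-target
#' samples only (post-target samples are zeros by construction); rows with
#' undefined correlations (constant segments) are flagged `NA` and should
#' be excluded from aggregation.
#'
#' @param epochs A preprocessed `epoch_set` (see [preprocess_epochs()]):
#'   cropped, filtered, z-scored, zeroed after target.
#' @param regressors Named list of `hazard_regressor`s (e.g. from
#'   [study_hazard_regressors()]) sampled at `epochs$fs` over the epoch
#'   window.
#' @param cfg A [ridge_config()].
#' @param min_samples Minimum number of pre-target samples required to
#'   compute a correlation, default 10.
#' @return A `score_table` data frame with columns `participant`, `trial`,
#'   `channel`, `training_condition`, `testing_condition`, `foreperiod`,
#'   `r`, `z`.
#' @export
loo_predict_scores <- function(epochs, regressors, cfg = ridge_config(),
                               min_samples = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_trials <- d[1]; n_chan <- d[2]; n_samp <- d[3]
  design <- build_lagged_design(regressors, n_samp, cfg)
  ch <- design_factor(design, cfg$lambda)
  tt <- epoch_times(epochs)
  conds <- sort(unique(as.character(epochs$trials$condition)))
  out <- vector("list", 0L)
  for (pp in unique(epochs$trials$participant)) {
    idx <- which(epochs$trials$participant == pp)
    trials <- epochs$trials[idx, , drop = FALSE]
    # all single-trial weights in one solve: samples x (trials*channels)
    Y <- matrix(aperm(epochs$data[idx, , , drop = FALSE], c(3, 1, 2)),
                nrow = n_samp)
    Wall <- ridge_solve(ch, design, Y)     # ncolS x (ntrials*nchan), trial-major
    nt <- length(idx)
    Warr <- array(Wall, dim = c(ncol(design), nt, n_chan))
    for (train_cond in conds) {
      in_train <- which(trials$condition == train_cond)
      if (length(in_train) < 2)
        stop("need at least 2 trials per training condition", call. = FALSE)
      Wsum <- apply(Warr[, in_train, , drop = FALSE], c(1, 3), sum)
      n_train <- length(in_train)
      # per test trial, the training-model weights
      Wbar <- array(0, dim = c(ncol(design), nt, n_chan))
      for (j in seq_len(nt)) {
        if (trials$condition[j] == train_cond) {
          Wbar[, j, ] <- (Wsum - Warr[, j, ]) / (n_train - 1L)
        } else {
          Wbar[, j, ] <- Wsum / n_train
        }
      }
      P <- design %*% matrix(Wbar, nrow = ncol(design))   # samples x (nt*nchan)
      for (j in seq_len(nt)) {
        k <- sum(tt <= trials$foreperiod[j] + 1e-9)
        cols <- j + nt * (seq_len(n_chan) - 1L)
        if (k < min_samples) {
          r <- rep(NA_real_, n_chan)
        } else {
          obs <- t(matrix(epochs$data[idx[j], , seq_len(k)], nrow = n_chan))
          r <- col_cors(P[, cols, drop = FALSE], obs, k)
        }
        out[[length(out) + 1L]] <- data.frame(
          participant = pp, trial = idx[j],
          channel = epochs$channels,
          training_condition = train_cond,
          testing_condition = as.character(trials$condition[j]),
          foreperiod = trials$foreperiod[j],
          r = r)
      }
    }
  }
  res <- do.call(rbind, out)
  res$z <- ifelse(is.na(res$r), NA_real_, fisher_z(res$r))
  rownames(res) <- NULL
  class(res) <- c("score_table", "data.frame")
  res
}

#' Per-trial correlation indices from a score table
#'
#' Joins, for every (participant, trial, channel), the scores of the models
#' trained on two contrasted conditions and computes the bounded
#' correlation index (see [correlation_index()]).
#'
#' @param scores A `score_table` from [loo_predict_scores()].
#' @param train_a,train_b Training conditions entering the index as `a`
#'   (positive pole) and `b`; defaults `"nonpredictive"` vs
#'   `"strongly_predictive"`.
#' @param on Passed to [correlation_index()].
#' @return Data frame with one row per (participant, trial, channel):
#'   `testing_condition`, `foreperiod`, `z_a`, `z_b`, `index`.
#' @export
score_indices <- function(scores, train_a = "nonpredictive",
                          train_b = "strongly_predictive", on = "z") {
  stopifnot(inherits(scores, "data.frame"))
  key <- function(df) paste(df$participant, df$trial, df$channel, sep = "\r")
  a <- scores[scores$training_condition == train_a, ]
  b <- scores[scores$training_condition == train_b, ]
  m <- match(key(a), key(b))
  ok <- !is.na(m)
  a <- a[ok, ]; b <- b[m[ok], ]
  data.frame(
    participant = a$participant, trial = a$trial, channel = a$channel,
    testing_condition = a$testing_condition, foreperiod = a$foreperiod,
    z_a = a$z, z_b = b$z,
    index = correlation_index(a$z, b$z, on = on))
}

#' Participant-by-electrode mean index matrix
#'
#' Aggregates per-trial indices to one value per participant and channel,
#' optionally restricted to one testing condition -- the input shape for
#' the cluster permutation test.
#'
#' @param indices Data frame from [score_indices()].
#' @param testing_condition Optional testing condition to restrict to.
#' @return Numeric matrix, participants x channels (dimnames set).
#' @export
index_matrix <- function(indices, testing_condition = NULL) {
  df <- indices
  if (!is.null(testing_condition))
    df <- df[df$testing_condition == testing_condition, ]
  df <- df[is.finite(df$index), ]
  tab <- tapply(df$index, list(df$participant, df$channel), mean)
  m <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  m
}

#' Summarise prediction scores
#'
#' Mean r (via mean Fisher z), t-based confidence interval and n per
#' (testing condition, training condition) cell, averaging over trials,
#' channels and participants.
#'
#' @param scores A `score_table`.
#' @param level Confidence level, default 0.95.
#' @return Data frame with one row per condition pair.
#' @export
summarize_scores <- function(scores, level = 0.95) {
  cells <- unique(scores[, c("testing_condition", "training_condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- scores$testing_condition == cells$testing_condition[i] &
      scores$training_condition == cells$training_condition[i]
    z <- scores$z[sel]
    ci <- correlation_ci(z, level)
    data.frame(testing_condition = cells$testing_condition[i],
               training_condition = cells$training_condition[i],
               mean_r = ci$mean_r, ci_lo_r = ci$ci_r[1], ci_hi_r = ci$ci_r[2],
               mean_z = ci$mean_z, n = ci$n)
  })
  out <- do.call(rbind, rows)
  out[order(out$testing_condition, out$training_condition), ]
}
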