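#' Ridge-regression configuration for TRF estimation
#'
#' @param lambda Unitless ridge parameter; the effective regulariser is
#'   `lambda * m` with `m` the mean diagonal of the design covariance, so
#'   `lambda` is scale-free. Default 4.
#' @param lag_min,lag_max Lag window (s) of the temporal response function;
#'   negative lags capture anticipatory weights. Defaults -0.2 and 0.6.
#' @return An object of class `ridge_config`.
#' @export
ridge_config <- function(lambda = 4, lag_min = -0.2, lag_max = 0.6) {
  stopifnot(lambda >= 0, lag_min < lag_max)
  structure(list(lambda = lambda, lag_min = lag_min, lag_max = lag_max),
            class = "ridge_config")
}

#' Build the lagged (time-shifted) design matrix
#'
#' Each regressor is expanded into one column per lag. With the sign
#' convention used throughout, a positive lag `tau` means the EEG at time
#' `t` reflects the regressor at `t - tau` (the regressor leads the
#' response); a negative lag lets the response precede the regressor.
#' Samples shifted outside the trial are zero-padded.
#'
#' @param regressors List of `hazard_regressor`s sharing `fs` and length
#'   (at least `trial_length` samples).
#' @param trial_length Number of response samples (design rows).
#' @param cfg A [ridge_config()].
#' @return A `lagged_design`: matrix of `trial_length` rows and
#'   `n_regressors * n_lags` columns, with attributes `lags` (s),
#'   `regressor_names`, `fs`.
#' @export
build_lagged_design <- function(regressors, trial_length, cfg = ridge_config()) {
  stopifnot(is.list(regressors), length(regressors) >= 1)
  fs <- regressors[[1]]$fs
  for (r in regressors) {
    stopifnot(inherits(r, "hazard_regressor"))
    if (r$fs != fs) stop("regressors must share fs", call. = FALSE)
    if (length(r$values) < trial_length)
      stop("regressor shorter than trial_length", call. = FALSE)
  }
  shift_min <- round(cfg$lag_min * fs)
  shift_max <- round(cfg$lag_max * fs)
  shifts <- shift_min:shift_max
  if (length(shifts) >= trial_length)
    stop("invalid-lags: lag span must be shorter than the trial", call. = FALSE)
  lags <- shifts / fs
  nm <- names(regressors)
  if (is.null(nm)) nm <- paste0("regressor", seq_along(regressors))
  S <- matrix(0, trial_length, length(regressors) * length(shifts))
  col <- 0L
  for (r in regressors) {
    v <- r$values[seq_len(trial_length)]
    for (sh in shifts) {
      col <- col + 1L
      if (sh >= 0) {
        if (sh < trial_length)
          S[(sh + 1L):trial_length, col] <- v[seq_len(trial_length - sh)]
      } else {
        if (-sh < trial_length)
          S[seq_len(trial_length + sh), col] <- v[(1L - sh):trial_length]
      }
    }
  }
  structure(S, lags = lags, regressor_names = nm, fs = fs,
            class = c("lagged_design", "matrix", "array"))
}

# Cholesky factor of the regularised normal-equation matrix
# S'S + lambda * m * I, with m the mean diagonal of S'S. Shared across
# trials that use the same design.
design_factor <- function(design, lambda) {
  StS <- crossprod(design)
  m <- mean(diag(StS))
  A <- StS + lambda * m * diag(nrow(StS))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    stop("rank-deficiency: the regularised system is singular; ",
         "use lambda > 0", call. = FALSE)
  ch
}

# Solve for weights given the Cholesky factor: columns of R are channels.
ridge_solve <- function(ch, design, R) {
  backsolve(ch, forwardsolve(t(ch), crossprod(design, R)))
}

new_trf <- function(weights, lags, regressor_names, channels,
                    lambda = NA_real_, resid_var = NULL) {
  structure(list(weights = weights, lags = lags,
                 regressor_names = regressor_names, channels = channels,
                 lambda = lambda, resid_var = resid_var),
            class = "trf")
}

#' @export
print.trf <- function(x, ...) {
  d <- dim(x$weights)
  cat("<trf> ", d[1], " lags [", min(x$lags), ", ", max(x$lags), "] s x ",
      d[2], " channels x ", d[3], " regressors (",
      paste(x$regressor_names, collapse = ", "), "), lambda = ",
      x$lambda, "\n", sep = "")
  invisible(x)
}

#' Fit a temporal response function by ridge regression
#'
#' Solves the regularised normal equations
#' `W = (S'S + lambda * m * I)^-1 S'R`, where `S` is the lagged design,
#' `R` the single-trial response (samples x channels), and `m` the mean of
#' the diagonal of `S'S` (so `lambda` is scale-free). At `lambda = 0` this
#' is ordinary least squares and requires a full-rank design.
#'
#' @param design A `lagged_design` (see [build_lagged_design()]).
#' @param response Numeric matrix, samples x channels (a vector is treated
#'   as one channel).
#' @param cfg A [ridge_config()].
#' @param channels Optional channel labels.
#' @return A `trf`: weights array lags x channels x regressors, plus lag
#'   axis, regressor names and per-channel residual variance.
#' @export
fit_trf <- function(design, response, cfg = ridge_config(), channels = NULL) {
  stopifnot(inherits(design, "lagged_design"))
  if (is.vector(response)) response <- matrix(response, ncol = 1)
  if (nrow(response) != nrow(design))
    stop("response sample count must equal the design row count", call. = FALSE)
  ch <- design_factor(design, cfg$lambda)
  Wmat <- ridge_solve(ch, design, response)           # (nreg*nlags) x channels
  lags <- attr(design, "lags")
  nms <- attr(design, "regressor_names")
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(ncol(response)))
  resid <- response - design %*% Wmat
  rv <- colMeans(resid^2)
  W <- aperm(array(Wmat, dim = c(length(lags), length(nms), ncol(response))),
             c(1, 3, 2))
  new_trf(W, lags, nms, channels, lambda = cfg$lambda, resid_var = rv)
}

#' Average temporal response functions
#'
#' Elementwise mean of TRFs sharing the same lag, channel and regressor
#' axes (e.g. over trials of a condition).
#'
#' @param trfs List of `trf` objects.
#' @return A `trf` with averaged weights.
#' @export
average_trfs <- function(trfs) {
  stopifnot(length(trfs) >= 1)
  ref <- trfs[[1]]
  for (x in trfs) {
    stopifnot(inherits(x, "trf"))
    if (!identical(dim(x$weights), dim(ref$weights)) ||
        !isTRUE(all.equal(x$lags, ref$lags)))
      stop("alignment error: TRF axes differ", call. = FALSE)
  }
  W <- Reduce(`+`, lapply(trfs, `[[`, "weights")) / length(trfs)
  new_trf(W, ref$lags, ref$regressor_names, ref$channels,
          lambda = ref$lambda)
}

#' Global field power of a TRF
#'
#' Reference-free spatial summary: the standard deviation of the TRF
#' weights across channels, per lag and regressor.
#'
#' @param trf A `trf` with at least 2 channels.
#' @return Matrix, lags x regressors, of across-channel SDs.
#' @export
global_field_power <- function(trf) {
  stopifnot(inherits(trf, "trf"))
  d <- dim(trf$weights)
  if (d[2] < 2)
    stop("undefined-GFP: global field power needs at least 2 channels",
         call. = FALSE)
  out <- apply(trf$weights, c(1, 3), stats::sd)
  dimnames(out) <- list(NULL, trf$regressor_names)
  out
}

#' Predict a trial from a TRF
#'
#' The forward model: the regressors (lag-expanded in `design`) are
#' convolved with the TRF weights, `prediction = S %*% W`, per channel.
#'
#' @param trf A `trf`.
#' @param design A `lagged_design` on the same lag grid.
#' @return Numeric matrix, samples x channels.
#' @export
predict_response <- function(trf, design) {
  stopifnot(inherits(trf, "trf"), inherits(design, "lagged_design"))
  if (!isTRUE(all.equal(attr(design, "lags"), trf$lags)) ||
      length(attr(design, "regressor_names")) != dim(trf$weights)[3])
    stop("alignment error: design and TRF axes differ", call. = FALSE)
  d <- dim(trf$weights)
  Wmat <- matrix(aperm(trf$weights, c(1, 3, 2)), nrow = d[1] * d[3])
  design %*% Wmat
}

#' Export a TRF as long-format CSV
#'
#' @param trf A `trf`.
#' @param path Output file; columns `lag_s`, `channel`, `regressor`,
#'   `weight`.
#' @return `path`, invisibly.
#' @export
write_trf_csv <- function(trf, path) {
  stopifnot(inherits(trf, "trf"))
  d <- dim(trf$weights)
  df <- data.frame(
    lag_s = rep(trf$lags, times = d[2] * d[3]),
    channel = rep(rep(trf$channels, each = d[1]), times = d[3]),
    regressor = rep(trf$regressor_names, each = d[1] * d[2]),
    weight = as.numeric(trf$weights))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
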