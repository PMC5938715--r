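#' Specify a foreperiod condition
#'
#' A condition is defined by the range and mean of its foreperiod
#' distribution, the number of discrete foreperiods drawn from it, and --
#' for the predictive (Gaussian) conditions -- the standard deviation of the
#' Gaussian plus a set of fixed additional foreperiods presented on top of
#' the Gaussian grid.
#'
#' @param label One of `"nonpredictive"`, `"weakly_predictive"`,
#'   `"strongly_predictive"`.
#' @param fp_min,fp_max,fp_mean Shortest, longest and mean foreperiod in
#'   seconds. Must satisfy `fp_min < fp_mean < fp_max`.
#' @param gaussian_sd Standard deviation (s) of the Gaussian foreperiod
#'   distribution; must be `NULL` exactly when `label = "nonpredictive"`.
#' @param n_grid Number of discrete foreperiods drawn from the distribution
#'   (grid points, excluding `additional_fps`).
#' @param additional_fps Numeric vector of fixed extra foreperiods (s),
#'   predictive conditions only; each must lie in `[fp_min, fp_max]`.
#' @param trials_per_block Total number of trials per experimental block for
#'   this condition (grid trials plus one trial per additional foreperiod).
#'
#' @return An object of class `condition_spec`.
#' @seealso [study_conditions()] for the three conditions of the reference
#'   design, [build_foreperiod_distribution()].
#' @export
condition_spec <- function(label,
                           fp_min, fp_max, fp_mean,
                           gaussian_sd = NULL,
                           n_grid,
                           additional_fps = numeric(0),
                           trials_per_block = NULL) {
  label <- match.arg(label,
                     c("nonpredictive", "weakly_predictive", "strongly_predictive"))
  stopifnot(is.numeric(fp_min), is.numeric(fp_max), is.numeric(fp_mean))
  if (!(fp_min < fp_mean && fp_mean < fp_max))
    stop("invalid-spec: need fp_min < fp_mean < fp_max", call. = FALSE)
  if (n_grid < 2)
    stop("invalid-spec: n_grid must be at least 2", call. = FALSE)
  if (identical(label, "nonpredictive")) {
    if (!is.null(gaussian_sd))
      stop("invalid-spec: gaussian_sd must be absent for the nonpredictive condition",
           call. = FALSE)
  } else {
    if (is.null(gaussian_sd) || gaussian_sd <= 0)
      stop("invalid-spec: predictive conditions need a positive gaussian_sd",
           call. = FALSE)
  }
  if (length(additional_fps) &&
      (any(additional_fps < fp_min) || any(additional_fps > fp_max)))
    stop("invalid-spec: additional foreperiods must lie in [fp_min, fp_max]",
         call. = FALSE)
  if (is.null(trials_per_block))
    trials_per_block <- n_grid + length(additional_fps)
  if (trials_per_block < n_grid + length(additional_fps))
    stop("invalid-spec: trials_per_block smaller than the number of distinct foreperiods",
         call. = FALSE)
  structure(
    list(label = label, fp_min = fp_min, fp_max = fp_max, fp_mean = fp_mean,
         gaussian_sd = gaussian_sd, n_grid = n_grid,
         additional_fps = sort(additional_fps),
         trials_per_block = as.integer(trials_per_block)),
    class = "condition_spec")
}

#' The three foreperiod conditions of the reference design
#'
#' Foreperiods range from 0.5 to 3.1 s with mean 1.8 s. The nonpredictive
#' condition uses 25 discrete foreperiods from a uniform distribution. The
#' weakly (SD 0.15 s) and strongly (SD 0.05 s) predictive conditions use 5
#' and 3 Gaussian grid points respectively, placed symmetrically about the
#' mean at multiples of the uniform-grid spacing, plus six fixed additional
#' foreperiods (0.50, 0.93, 1.37, 2.23, 2.67, 3.10 s). Per-block trial
#' totals are 25, 32 and 34.
#'
#' @return Named list of three [condition_spec()] objects
#'   (`nonpredictive`, `weakly_predictive`, `strongly_predictive`).
#' @export
study_conditions <- function() {
  extra <- c(0.50, 0.93, 1.37, 2.23, 2.67, 3.10)
  list(
    nonpredictive = condition_spec(
      "nonpredictive", fp_min = 0.5, fp_max = 3.1, fp_mean = 1.8,
      n_grid = 25, trials_per_block = 25),
    weakly_predictive = condition_spec(
      "weakly_predictive", fp_min = 0.5, fp_max = 3.1, fp_mean = 1.8,
      gaussian_sd = 0.15, n_grid = 5, additional_fps = extra,
      trials_per_block = 32),
    strongly_predictive = condition_spec(
      "strongly_predictive", fp_min = 0.5, fp_max = 3.1, fp_mean = 1.8,
      gaussian_sd = 0.05, n_grid = 3, additional_fps = extra,
      trials_per_block = 34))
}

# Largest-remainder apportionment of `total` counts proportional to `w`,
# with every cell getting at least `min_each`.
allocate_counts <- function(w, total, min_each = 1L) {
  k <- length(w)
  if (total < k * min_each)
    stop("invalid-spec: cannot allocate ", total, " trials over ", k,
         " foreperiods with at least ", min_each, " each", call. = FALSE)
  target <- w / sum(w) * (total - k * min_each)
  base <- floor(target)
  rem <- total - k * min_each - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base + min_each)
}

#' Build the discrete foreperiod distribution of a condition
#'
#' For the nonpredictive condition the distribution is `n_grid` equally
#' spaced foreperiods on `[fp_min, fp_max]` with equal probability. For
#' predictive conditions the Gaussian grid points (symmetric about the mean,
#' spaced at the uniform-grid step) receive per-block trial counts allocated
#' proportionally to the Gaussian density (largest-remainder rounding so the
#' block total is met exactly); each additional foreperiod contributes one
#' trial per block. Probabilities are the per-foreperiod trial counts
#' normalised to sum to 1.
#'
#' @param spec A [condition_spec()].
#' @param grid_step Spacing (s) of the Gaussian grid; defaults to the
#'   uniform-grid spacing of the reference design,
#'   `(fp_max - fp_min) / (25 - 1)`.
#' @return An object of class `fp_distribution`: list with `times`
#'   (ascending, s), `probs` (sum to 1), `cum` (cumulative, inclusive of the
#'   mass at each time), `counts` (per-block trial multiplicities) and
#'   `label`.
#' @export
build_foreperiod_distribution <- function(spec, grid_step = NULL) {
  stopifnot(inherits(spec, "condition_spec"))
  if (identical(spec$label, "nonpredictive")) {
    times <- seq(spec$fp_min, spec$fp_max, length.out = spec$n_grid)
    counts <- rep.int(1L, spec$n_grid)
  } else {
    if (is.null(grid_step))
      grid_step <- (spec$fp_max - spec$fp_min) / (25 - 1)
    half <- (spec$n_grid - 1) / 2
    grid <- spec$fp_mean + (-half:half) * grid_step
    if (any(grid < spec$fp_min) || any(grid > spec$fp_max))
      stop("invalid-spec: Gaussian grid exceeds the foreperiod range", call. = FALSE)
    n_grid_trials <- spec$trials_per_block - length(spec$additional_fps)
    dens <- stats::dnorm(grid, mean = spec$fp_mean, sd = spec$gaussian_sd)
    grid_counts <- allocate_counts(dens, n_grid_trials)
    times <- c(grid, spec$additional_fps)
    counts <- c(grid_counts, rep.int(1L, length(spec$additional_fps)))
    ord <- order(times)
    times <- times[ord]
    counts <- counts[ord]
  }
  if (any(duplicated(times)))
    stop("invalid-spec: duplicated foreperiod values", call. = FALSE)
  probs <- counts / sum(counts)
  structure(
    list(times = times, probs = probs, cum = cumsum(probs),
         counts = counts, label = spec$label),
    class = "fp_distribution")
}

#' @export
print.fp_distribution <- function(x, ...) {
  cat("<fp_distribution> ", x$label, ": ", length(x$times),
      " discrete foreperiods in [", min(x$times), ", ", max(x$times),
      "] s, mean ", round(sum(x$times * x$probs), 4), " s\n", sep = "")
  invisible(x)
}

#' Read condition specifications from a plain-text config file
#'
#' The file is YAML-style key-value text: a top-level map of condition
#' names, each with fields matching the arguments of [condition_spec()].
#'
#' @param path Path to the config file.
#' @return Named list of [condition_spec()] objects.
#' @export
read_condition_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cc) {
    condition_spec(label = cc$label,
                   fp_min = cc$fp_min, fp_max = cc$fp_max, fp_mean = cc$fp_mean,
                   gaussian_sd = cc$gaussian_sd,
                   n_grid = cc$n_grid,
                   additional_fps = if (is.null(cc$additional_fps)) numeric(0)
                                    else as.numeric(cc$additional_fps),
                   trials_per_block = cc$trials_per_block)
  })
}
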