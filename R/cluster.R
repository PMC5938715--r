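#' k-nearest-neighbour channel adjacency
#'
#' Builds a symmetric channel neighbourhood graph from 2-D sensor
#' coordinates: each channel is connected to its `k` nearest neighbours
#' (union over both directions, so the graph is undirected).
#'
#' @param coords Numeric matrix, channels x 2, of sensor positions.
#' @param k Number of nearest neighbours, default 4.
#' @param labels Optional channel labels (dimnames).
#' @return A logical adjacency matrix (channels x channels, zero diagonal)
#'   of class `channel_adjacency`.
#' @export
knn_adjacency <- function(coords, k = 4, labels = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  n <- nrow(coords)
  k <- min(k, n - 1L)
  D <- as.matrix(stats::dist(coords))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[-1][seq_len(k)]
    A[i, nb] <- TRUE
  }
  A <- A | t(A)
  diag(A) <- FALSE
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  class(A) <- c("channel_adjacency", class(A))
  A
}

#' Read a channel adjacency from an edge-list CSV
#'
#' @param path CSV with columns `from`, `to` (channel labels).
#' @param labels Character vector of all channel labels (defines order and
#'   isolated channels).
#' @return A logical adjacency matrix of class `channel_adjacency`.
#' @export
read_adjacency_csv <- function(path, labels) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(e)))
  n <- length(labels)
  A <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  i <- match(e$from, labels); j <- match(e$to, labels)
  if (anyNA(i) || anyNA(j))
    stop("edge list refers to unknown channel labels", call. = FALSE)
  A[cbind(i, j)] <- TRUE
  A <- A | t(A)
  diag(A) <- FALSE
  class(A) <- c("channel_adjacency", class(A))
  A
}

# Connected components of the suprathreshold electrode set under the
# adjacency list `nb` (list of integer neighbour vectors). Hand-rolled BFS:
# runs inside the permutation loop, so it must be allocation-light.
supra_clusters <- function(supra, nb) {
  members <- which(supra)
  if (!length(members)) return(list())
  seen <- logical(length(nb))
  out <- list()
  for (s in members) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (w in nb[[v]]) {
        if (supra[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# One-sample t statistics per column of X (participants x electrodes),
# given optional per-row signs. Vectorised over permutations when `signs`
# is a matrix (n_perm x participants): returns n_perm x electrodes.
col_tstat <- function(X, signs = NULL) {
  n <- nrow(X)
  if (is.null(signs)) {
    m <- colMeans(X)
    s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
    return(m / (s / sqrt(n)))
  }
  M <- (signs %*% X) / n                       # n_perm x electrodes
  ssq <- matrix(colSums(X^2), nrow(M), ncol(M), byrow = TRUE)
  S <- sqrt(pmax(ssq - n * M^2, 0) / (n - 1))
  M / (S / sqrt(n))
}

# Max positive / min negative cluster mass of a t-vector.
max_cluster_masses <- function(t_vec, t_crit, nb) {
  pos <- supra_clusters(t_vec > t_crit, nb)
  neg <- supra_clusters(t_vec < -t_crit, nb)
  c(pos = if (length(pos)) max(vapply(pos, function(cc) sum(t_vec[cc]), 0)) else 0,
    neg = if (length(neg)) min(vapply(neg, function(cc) sum(t_vec[cc]), 0)) else 0)
}

#' Cluster-based permutation test across electrodes
#'
#' Second-level one-sample test of participant-by-electrode values (e.g.
#' correlation-index contrasts) against zero. Electrodes whose one-sample t
#' exceeds the two-tailed `alpha` threshold form clusters of adjacent
#' channels; each cluster's mass is the sum of its t values. The null
#' distribution of the maximal cluster mass is built by random sign flips
#' of whole participants; each observed cluster gets a Monte-Carlo p from
#' its tail's null, doubled for the two-tailed decision (capped at 1), so
#' a single reported p is compared against `alpha`-style levels directly.
#'
#' @param indices Numeric matrix, participants x electrodes.
#' @param adjacency Logical adjacency matrix (see [knn_adjacency()]).
#' @param alpha Cluster-forming threshold (two-tailed tail probability per
#'   side), default 0.025.
#' @param n_perm Number of sign-flip permutations, default 1000.
#' @param seed Optional integer seed for reproducibility.
#' @return A `cluster_result`: list with `clusters` (each: `channels`,
#'   `mass`, `sign`, `p_tail` -- the one-tailed Monte-Carlo p, minimum
#'   `1/(n_perm+1)` -- and `p`, its doubled two-tailed version), `t`
#'   (per-electrode t), `t_crit`, `alpha`, `n_perm`, and `min_p` (smallest
#'   two-tailed cluster p; 1 if no cluster).
#' @export
cluster_permutation_test <- function(indices, adjacency, alpha = 0.025,
                                     n_perm = 1000, seed = NULL) {
  stopifnot(is.matrix(indices), nrow(indices) >= 2)
  ne <- ncol(indices)
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ne, ncol(adjacency) == ne)
  if (n_perm < 100)
    warning("fewer than 100 permutations: p-values are coarse", call. = FALSE)
  nb <- apply(adjacency, 1, which, simplify = FALSE)
  if (any(vapply(nb, length, 0L) == 0) && ne > 1)
    warning("adjacency graph has isolated electrodes", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(indices)
  t_obs <- col_tstat(indices)
  t_crit <- stats::qt(1 - alpha, df = n - 1)
  pos <- supra_clusters(t_obs > t_crit, nb)
  neg <- supra_clusters(t_obs < -t_crit, nb)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_perm <- col_tstat(indices, signs)
  null_mass <- t(apply(t_perm, 1, max_cluster_masses, t_crit = t_crit, nb = nb))
  clusters <- list()
  add_cluster <- function(cc, sign) {
    mass <- sum(t_obs[cc])
    exceed <- if (sign > 0) sum(null_mass[, "pos"] >= mass)
              else sum(null_mass[, "neg"] <= mass)
    p_tail <- (exceed + 1) / (n_perm + 1)
    list(channels = if (!is.null(colnames(indices))) colnames(indices)[cc] else cc,
         electrode_index = cc, mass = mass, sign = sign,
         p_tail = p_tail, p = min(1, 2 * p_tail))
  }
  for (cc in pos) clusters[[length(clusters) + 1L]] <- add_cluster(cc, 1)
  for (cc in neg) clusters[[length(clusters) + 1L]] <- add_cluster(cc, -1)
  min_p <- if (length(clusters)) min(vapply(clusters, `[[`, 0, "p")) else 1
  structure(list(clusters = clusters, t = t_obs, t_crit = t_crit,
                 alpha = alpha, n_perm = n_perm, min_p = min_p),
            class = "cluster_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), ",
      x$n_perm, " permutations, forming threshold |t| > ",
      signif(x$t_crit, 4), "\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: %d electrode(s), mass %.2f, p = %.4f\n",
                if (cl$sign > 0) "positive" else "negative",
                length(cl$electrode_index), cl$mass, cl$p))
  invisible(x)
}

#' Write a cluster test result as JSON
#'
#' @param x A `cluster_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(x, path) {
  stopifnot(inherits(x, "cluster_result"))
  out <- list(
    n_perm = x$n_perm, alpha = x$alpha, t_crit = x$t_crit, min_p = x$min_p,
    clusters = lapply(x$clusters, function(cl)
      list(channels = cl$channels, mass = cl$mass,
           sign = cl$sign, p = cl$p)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
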