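# Group-level inference: sign-flip cluster permutation tests on timecourses.
#
# The null hypothesis is that per-subject scores are symmetrically
# distributed around zero, so randomly negating whole subjects leaves the
# distribution unchanged. Observed clusters are contiguous runs of
# suprathreshold t values; their summed t is compared with the maximum
# cluster sum obtained under random sign flips (max-statistic correction
# across time).

new_cluster_result <- function(clusters, n_perm, threshold, tail) {
  structure(list(clusters = clusters, n_permutations = n_perm,
                 threshold = threshold, tail = tail),
            class = "phonseq_clusters")
}

#' @export
print.phonseq_clusters <- function(x, ...) {
  cat(sprintf("<phonseq_clusters> %d cluster(s), threshold |t| > %.2f, %d permutations\n",
              nrow(x$clusters), x$threshold, x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# t statistics per column for every sign-flip pattern at once.
# scores: n x T; signs: n_perm x n of +/-1. Squares are flip-invariant, so
# only the means change across permutations.
flip_tstats <- function(scores, signs) {
  n <- nrow(scores)
  mu <- signs %*% scores / n                     # n_perm x T
  ssq <- matrix(colSums(scores^2), nrow(signs), ncol(scores), byrow = TRUE)
  sd_ <- sqrt(pmax(ssq - n * mu^2, 0) / (n - 1))
  mu / (sd_ / sqrt(n))
}

# Clusters of a t timecourse: contiguous runs with t beyond threshold,
# keeping positive and negative runs separate. Returns start/end indices and
# summed t.
t_clusters <- function(tvals, threshold, tail) {
  out <- list()
  if (tail %in% c("two", "greater")) {
    runs <- true_runs(tvals > threshold)
    if (length(runs)) for (r in seq_len(nrow(runs))) {
      out[[length(out) + 1]] <- c(runs[r, 1], runs[r, 2],
                                  sum(tvals[runs[r, 1]:runs[r, 2]]))
    }
  }
  if (tail %in% c("two", "less")) {
    runs <- true_runs(tvals < -threshold)
    if (length(runs)) for (r in seq_len(nrow(runs))) {
      out[[length(out) + 1]] <- c(runs[r, 1], runs[r, 2],
                                  sum(tvals[runs[r, 1]:runs[r, 2]]))
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' One-sample sign-flip cluster permutation test
#'
#' Tests whether a subjects x time score matrix differs from zero anywhere
#' in time, correcting across timepoints by the max-cluster-sum statistic.
#'
#' @param scores numeric matrix, subjects x timepoints.
#' @param n_perm number of random sign-flip permutations (default 10000).
#' @param threshold cluster-forming t threshold; default is the two-tailed
#'   p = 0.05 critical t at `df = nrow(scores) - 1`.
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @param times optional time grid (s) used to report cluster extents in ms.
#' @param seed integer seed.
#' @return a `phonseq_clusters` object; `clusters` is a tibble with
#'   `start`, `end` (indices), `start_ms`, `end_ms` (if `times` given),
#'   `sum_t` and `p` (reporting floor `1 / n_perm`).
#' @export
one_sample_cluster_test <- function(scores, n_perm = 10000, threshold = NULL,
                                    tail = c("two", "greater", "less"),
                                    times = NULL, seed = NULL) {
  tail <- match.arg(tail)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 5) abort("need at least 5 subjects")
  if (!all(is.finite(scores))) abort("scores must be finite")
  if (all(col_sds(scores) == 0)) abort("constant scores")
  if (n_perm < 100) warn("fewer than 100 permutations; p values are coarse")
  if (is.null(threshold)) threshold <- stats::qt(0.975, df = n - 1)

  tobs <- colMeans(scores) / (col_sds(scores) / sqrt(n))
  obs <- t_clusters(tobs, threshold, tail)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    tperm <- flip_tstats(scores, signs)
    null_max <- vapply(seq_len(n_perm), function(i) {
      cl <- t_clusters(tperm[i, ], threshold, tail)
      if (is.null(cl)) 0 else max(abs(cl[, 3]))
    }, numeric(1))
    if (is.null(obs)) {
      clusters <- tibble::tibble(start = integer(0), end = integer(0),
                                 sum_t = numeric(0), p = numeric(0))
    } else {
      p <- vapply(obs[, 3], function(s) {
        # numerically tolerant ">=" so exact mirror flips count as ties
        max(mean(null_max >= abs(s) * (1 - 1e-10) - 1e-12), 1 / n_perm)
      }, numeric(1))
      clusters <- tibble::tibble(start = as.integer(obs[, 1]),
                                 end = as.integer(obs[, 2]),
                                 sum_t = obs[, 3], p = p)
    }
    if (!is.null(times)) {
      clusters$start_ms <- 1000 * times[clusters$start]
      clusters$end_ms <- 1000 * times[clusters$end]
    }
    new_cluster_result(clusters, n_perm, threshold, tail)
  })
}

#' Two-condition (paired) cluster permutation test
#'
#' Sign-flip cluster test on the paired per-subject differences
#' `scores_a - scores_b`.
#'
#' @param scores_a,scores_b subjects x time matrices with matching shapes
#'   (paired subjects).
#' @inheritParams one_sample_cluster_test
#' @return a `phonseq_clusters` object.
#' @export
two_condition_cluster_test <- function(scores_a, scores_b, n_perm = 10000,
                                       threshold = NULL,
                                       tail = c("two", "greater", "less"),
                                       times = NULL, seed = NULL) {
  if (!identical(dim(as.matrix(scores_a)), dim(as.matrix(scores_b)))) {
    abort("paired score matrices must have identical shapes")
  }
  one_sample_cluster_test(as.matrix(scores_a) - as.matrix(scores_b),
                          n_perm = n_perm, threshold = threshold,
                          tail = tail, times = times, seed = seed)
}

#' Spearman rank correlation with a permutation p value
#'
#' Midrank-based rank correlation; the p value is the fraction of label
#' permutations with `|rho|` at least as large as observed (reporting floor
#' `1 / n_perm`).
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y, n_perm = 10000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 4) {
    abort("x and y must have equal length >= 4")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      stats::cor(rx, sample(ry))
    }, numeric(1))
    list(rho = rho, p = max(mean(abs(null) >= abs(rho)), 1 / n_perm))
  })
}
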