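# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a B2B result
#'
#' @param x a [b2b_timecourse()] result.
#' @param ... unused.
#' @return tibble with `feature`, `time`, `beta` and (after
#'   [variance_shares()]) `rhat`.
#' @export
tidy.phonseq_b2b <- function(x, ...) {
  out <- tibble::tibble(
    feature = rep(rownames(x$beta), times = ncol(x$beta)),
    time = rep(x$times, each = nrow(x$beta)),
    beta = as.vector(x$beta)
  )
  if (!is.null(x$rhat)) out$rhat <- as.vector(x$rhat)
  out
}

#' @export
glance.phonseq_b2b <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$beta), n_times = ncol(x$beta),
                 n_splits = x$n_splits,
                 ceiling = x$ceiling %||% NA_real_)
}

#' Tidy a temporal-generalisation surface
#'
#' @param x a `phonseq_tg`.
#' @param ... unused.
#' @return tibble with `train_time`, `test_time` (s; test includes any
#'   word-clock shift), `score`.
#' @export
tidy.phonseq_tg <- function(x, ...) {
  tibble::tibble(
    train_time = rep(x$times, times = length(x$times)),
    test_time = rep(x$times + x$shift_ms / 1000, each = length(x$times)),
    score = as.vector(x$score)
  )
}

#' @export
tidy.phonseq_clusters <- function(x, ...) x$clusters

#' @export
glance.phonseq_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
                 threshold = x$threshold, n_permutations = x$n_permutations)
}

#' @export
tidy.phonseq_latency <- function(x, ...) x$predictions

#' @export
glance.phonseq_latency <- function(x, ...) {
  tibble::tibble(r = x$r, r_within_fold = x$r_within_fold,
                 n_obs = nrow(x$predictions),
                 mean_predicted_ms = mean(x$predictions$predicted_ms),
                 folds = x$folds, alpha = x$alpha)
}
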