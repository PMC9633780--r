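# Back-to-back (B2B) ridge regression.
#
# Two-stage, covariate-controlled decoding. On a random half of trials a
# ridge decoder G is trained per feature across channels; on the held half
# each decoded feature is regressed on ALL true features with a second ridge
# (the encoder H). The diagonal of H measures the unique contribution of a
# feature to its own decoding: it tends to a positive value if and only if
# the feature is linearly and specifically encoded, not merely correlated
# with an encoded covariate. Betas are averaged over many shuffled splits to
# stabilise coefficients of correlated regressors.

check_b2b_inputs <- function(X, Y) {
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have aligned rows")
  n <- nrow(X); F_ <- ncol(Y)
  if (n < 2 * F_) {
    abort(sprintf("too few trials: need at least 2 per feature (%d features, %d trials)",
                  F_, n))
  }
  sds <- col_sds(Y)
  if (any(sds == 0)) {
    bad <- colnames(Y)[sds == 0] %||% which(sds == 0)
    abort(sprintf("constant feature column: %s", paste(bad, collapse = ", ")))
  }
  Y
}

b2b_splits <- function(n, n_splits, seed) {
  with_seed(seed, {
    lapply(seq_len(n_splits), function(s) sample.int(n, floor(n / 2)))
  })
}

#' Back-to-back regression at a single timepoint
#'
#' @param X trials x channels matrix of activity at one timepoint.
#' @param Y trials x features matrix of true features (+/-1 binary,
#'   z-scored continuous).
#' @param n_splits number of random 50/50 train/test splits to average
#'   (default 100).
#' @param seed integer seed governing the splits.
#' @param alphas_G,alphas_H regularisation grids for decoder and encoder
#'   (default 20 log-spaced values in `[1e-5, 1e+5]`, selected per target by
#'   leave-one-out CV). Use `0` for unregularised fits.
#' @param splits optional list of training-index vectors, overriding the
#'   random splits (each a subset of trials; the remainder is the encoder
#'   half).
#' @param direction `"decoded_on_true"` (default) regresses each decoded
#'   feature on all true features; `"true_on_decoded"` is the transposed
#'   alternative.
#' @return list with `beta` (named length-F vector, averaged over splits),
#'   `beta_splits` (n_splits x F), and the median selected decoder alpha per
#'   feature.
#' @export
fit_b2b_at_time <- function(X, Y, n_splits = 100, seed = NULL,
                            alphas_G = ridge_alpha_grid(),
                            alphas_H = ridge_alpha_grid(),
                            splits = NULL,
                            direction = c("decoded_on_true", "true_on_decoded")) {
  direction <- match.arg(direction)
  Y <- check_b2b_inputs(X, Y)
  n <- nrow(X); F_ <- ncol(Y)
  if (is.null(splits)) splits <- b2b_splits(n, n_splits, seed)
  beta_splits <- matrix(NA_real_, length(splits), F_,
                        dimnames = list(NULL, colnames(Y)))
  alpha_g <- matrix(NA_real_, length(splits), F_)
  for (s in seq_along(splits)) {
    tr <- splits[[s]]
    te <- setdiff(seq_len(n), tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- col_sds(X[tr, , drop = FALSE])
    Xtr <- scale_by(X[tr, , drop = FALSE], mu, sd_)
    Xte <- scale_by(X[te, , drop = FALSE], mu, sd_)
    G <- ridge_cv(Xtr, Y[tr, , drop = FALSE], alphas = alphas_G)
    Yhat <- ridge_predict(G, Xte)
    if (direction == "decoded_on_true") {
      H <- ridge_cv(Y[te, , drop = FALSE], Yhat, alphas = alphas_H)
    } else {
      H <- ridge_cv(Yhat, Y[te, , drop = FALSE], alphas = alphas_H)
    }
    beta_splits[s, ] <- diag(H$coef)
    alpha_g[s, ] <- G$alpha
  }
  list(beta = colMeans(beta_splits), beta_splits = beta_splits,
       alpha_G = apply(alpha_g, 2, stats::median))
}

#' Per-timepoint B2B beta timecourses
#'
#' Applies [fit_b2b_at_time()] independently at every sample of the epoch
#' grid. Per-timepoint seeds are derived from the master seed by counter, so
#' any timepoint can be recomputed in isolation and results are independent
#' of execution order.
#'
#' @param epochs an [epoch_set()].
#' @param Y trials x features matrix/tibble, row-aligned with the epochs.
#' @inheritParams fit_b2b_at_time
#' @return object of class `phonseq_b2b`: `beta` (features x time), `times`,
#'   `n_splits`, `seed`; `rhat`/`ceiling` are filled in by
#'   [variance_shares()].
#' @export
b2b_timecourse <- function(epochs, Y, n_splits = 100, seed = NULL,
                           alphas_G = ridge_alpha_grid(),
                           alphas_H = ridge_alpha_grid()) {
  Y <- check_b2b_inputs(at_time(epochs, 1), Y)
  n_t <- length(epochs$times)
  beta <- matrix(NA_real_, ncol(Y), n_t,
                 dimnames = list(colnames(Y), NULL))
  for (tt in seq_len(n_t)) {
    fit <- fit_b2b_at_time(at_time(epochs, tt), Y, n_splits = n_splits,
                           seed = child_seed(seed, tt),
                           alphas_G = alphas_G, alphas_H = alphas_H)
    beta[, tt] <- fit$beta
  }
  structure(list(beta = beta, times = epochs$times, n_splits = n_splits,
                 seed = seed, features = colnames(Y),
                 ceiling = NULL, rhat = NULL),
            class = "phonseq_b2b")
}

#' @export
print.phonseq_b2b <- function(x, ...) {
  cat(sprintf("<phonseq_b2b> %d features x %d timepoints (%d splits)\n",
              nrow(x$beta), ncol(x$beta), x$n_splits))
  invisible(x)
}

#' Noise ceiling and normalised variance shares
#'
#' The noise ceiling is the maximum over time of the summed betas across all
#' features; each feature timecourse is divided by it, so the shares sum to
#' exactly 1 at the ceiling timepoint.
#'
#' @param result a [b2b_timecourse()] result.
#' @return the result with `ceiling` (scalar) and `rhat` (features x time)
#'   filled in.
#' @export
variance_shares <- function(result) {
  if (is.null(result$beta)) abort("no beta timecourses present")
  total <- colSums(result$beta)
  ceiling_ <- max(total)
  if (ceiling_ <= 0) abort("uninformative fit: noise ceiling is not positive")
  result$ceiling <- ceiling_
  result$rhat <- result$beta / ceiling_
  result
}

# Exact rank-based AUC (Mann-Whitney statistic).
auc_stat <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated AUC decoding timecourse
#'
#' A plain single-feature ridge decoder scored with the area under the ROC
#' curve at every timepoint, for comparison with B2B betas. Chance is 0.5.
#'
#' @param epochs an [epoch_set()].
#' @param y binary feature vector (+/-1 or 0/1), one value per trial.
#' @param folds number of stratified CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param alphas decoder regularisation grid.
#' @return tibble with columns `time` and `auc`.
#' @export
auc_decode <- function(epochs, y, folds = 5, seed = NULL,
                       alphas = ridge_alpha_grid()) {
  y <- as.numeric(y)
  cls <- sort(unique(y))
  if (length(cls) != 2) abort("`y` must be binary")
  if (min(table(y)) < folds) {
    abort("single-class fold risk: fewer minority-class trials than folds")
  }
  n_t <- length(epochs$times)
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    auc <- numeric(n_t)
    for (tt in seq_len(n_t)) {
      Xt <- at_time(epochs, tt)
      fold_auc <- numeric(folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        if (length(unique(y[tr])) < 2) abort("single-class training fold")
        mu <- colMeans(Xt[tr, , drop = FALSE])
        sd_ <- col_sds(Xt[tr, , drop = FALSE])
        fit <- ridge_cv(scale_by(Xt[tr, , drop = FALSE], mu, sd_),
                        y[tr], alphas = alphas)
        dec <- ridge_predict(fit, scale_by(Xt[!tr, , drop = FALSE], mu, sd_))
        fold_auc[k] <- auc_stat(dec, y[!tr] == cls[2])
      }
      auc[tt] <- mean(fold_auc)
    }
    tibble::tibble(time = epochs$times, auc = auc)
  })
}
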