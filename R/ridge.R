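# SVD-based ridge regression with efficient multi-alpha leave-one-out CV.
#
# All decoders in this package reduce to ridge fits on modest matrices, fitted
# many thousands of times (per timepoint, per split).  Solving through a single
# SVD of the design lets every regularisation strength on the grid be evaluated
# at negligible extra cost, and gives closed-form leave-one-out residuals, so
# the per-target alpha is chosen without refitting.

#' Default regularisation grid for decoders
#'
#' Twenty log-spaced values spanning `1e-5` to `1e+5`, the grid used by the
#' back-to-back decoding and encoding stages.
#'
#' @param n number of grid points.
#' @param lo,hi grid end points.
#' @return numeric vector of length `n`.
#' @export
ridge_alpha_grid <- function(n = 20, lo = 1e-5, hi = 1e+5) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# Fit ridge coefficients for one or more targets at fixed alpha.
# X: n x p, Y: n x m (or vector). Returns list(coef = p x m, intercept = m).
ridge_solve <- function(X, Y, alpha, intercept = TRUE) {
  Y <- as.matrix(Y)
  if (intercept) {
    xbar <- colMeans(X); ybar <- colMeans(Y)
    Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  } else {
    xbar <- rep(0, ncol(X)); ybar <- rep(0, ncol(Y))
    Xc <- X; Yc <- Y
  }
  sv <- svd(Xc)
  d <- sv$d
  keep <- d > max(d[1], 0) * 1e-12
  if (alpha == 0 && !all(keep)) {
    d <- d[keep]; sv$u <- sv$u[, keep, drop = FALSE]; sv$v <- sv$v[, keep, drop = FALSE]
  }
  shrink <- d / (d^2 + alpha)
  coef <- sv$v %*% (shrink * crossprod(sv$u, Yc))
  b0 <- ybar - drop(crossprod(coef, xbar))
  list(coef = coef, intercept = b0)
}

# Precompute the SVD of a design matrix so that many target sets can be
# fitted against the same design (e.g. the encoder stage of temporal
# generalisation, where the true-feature design is fixed across test times).
ridge_design <- function(X, intercept = TRUE) {
  xbar <- if (intercept) colMeans(X) else rep(0, ncol(X))
  Xc <- if (intercept) sweep(X, 2, xbar) else X
  sv <- svd(Xc)
  list(sv = sv, xbar = xbar, n = nrow(X), p = ncol(X), intercept = intercept)
}

# Ridge with per-target alpha selection by closed-form leave-one-out CV.
#
# X: n x p design (or a ridge_design()); Y: n x m targets.
# Returns list(coef p x m, intercept m, alpha m, loo_mse length(alphas) x m).
ridge_cv <- function(X, Y, alphas = ridge_alpha_grid(), intercept = TRUE) {
  des <- if (is.list(X) && !is.null(X$sv)) X else ridge_design(X, intercept)
  Y <- as.matrix(Y)
  n <- des$n; m <- ncol(Y)
  intercept <- des$intercept
  ybar <- if (intercept) colMeans(Y) else rep(0, m)
  Yc <- if (intercept) sweep(Y, 2, ybar) else Y
  xbar <- des$xbar
  sv <- des$sv
  d <- sv$d
  UtY <- crossprod(sv$u, Yc)                 # r x m
  U2 <- sv$u^2                               # n x r
  loo_mse <- matrix(NA_real_, length(alphas), m)
  h_base <- if (intercept) 1 / n else 0
  pos <- d > max(d[1], 0) * 1e-12
  for (k in seq_along(alphas)) {
    a <- alphas[k]
    w <- ifelse(pos | a > 0, d^2 / (d^2 + a), 0)   # shrinkage factors
    fit <- sv$u %*% (w * UtY)                # n x m fitted values (centered)
    h <- drop(U2 %*% w) + h_base             # leverage per observation
    h <- pmin(h, 1 - 1e-10)
    res <- (Yc - fit) / (1 - h)
    loo_mse[k, ] <- colMeans(res^2)
  }
  best <- apply(loo_mse, 2, which.min)
  coef <- matrix(0, des$p, m)
  for (k in unique(best)) {
    idx <- which(best == k)
    shrink <- ifelse(pos | alphas[k] > 0, d / (d^2 + alphas[k]), 0)
    coef[, idx] <- sv$v %*% (shrink * UtY[, idx, drop = FALSE])
  }
  b0 <- ybar - drop(crossprod(coef, xbar))
  list(coef = coef, intercept = b0, alpha = alphas[best], loo_mse = loo_mse)
}

ridge_predict <- function(fit, X) {
  sweep(X %*% fit$coef, 2, fit$intercept, "+")
}
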