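# Coefficient-topography trajectories and the latency-since-onset decoder.

#' Unregularised per-timepoint decoding coefficients
#'
#' Ordinary least squares (ridge with zero regularisation) decoding weights
#' at each timepoint, fitted on all trials with no cross-validation: the goal
#' is interpretable coefficient topographies, not out-of-sample prediction.
#'
#' @param epochs an [epoch_set()].
#' @param Y trials x features matrix/tibble.
#' @return array features x channels x time, dimnames on the feature axis.
#' @export
unregularized_coefficients <- function(epochs, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y); n_ch <- dim(epochs$X)[2]
  if (n < 2 * n_ch) {
    abort("too few trials for unregularised coefficients (need trials >> channels); use a regularised decoder instead")
  }
  n_t <- length(epochs$times)
  W <- array(NA_real_, dim = c(ncol(Y), n_ch, n_t),
             dimnames = list(colnames(Y), NULL, NULL))
  for (tt in seq_len(n_t)) {
    Xt <- at_time(epochs, tt)
    sv <- svd(sweep(Xt, 2, colMeans(Xt)))
    if (min(sv$d) < max(sv$d) * 1e-10) {
      abort("rank-deficient channel matrix; coefficients are not identifiable")
    }
    fit <- ridge_solve(Xt, Y, alpha = 0)
    W[, , tt] <- t(fit$coef)
  }
  W
}

# Binary half-space masks over the sensor layout, normalised to unit norm.
layout_masks <- function(layout) {
  ym <- as.numeric(layout$y > 0)           # anterior = 1
  xm <- as.numeric(layout$x > 0)           # right = 1
  list(y = ym / sqrt(sum(ym^2)), x = xm / sqrt(sum(xm^2)))
}

#' Project coefficient topographies onto sensor-axis masks
#'
#' Takes the root mean square of the coefficients across subjects (absolute
#' magnitudes; topography signs are ambiguous), then computes the cosine
#' projection of each timepoint's topography against a binary
#' anterior/posterior mask (y) and a binary left/right mask (x), each
#' normalised to unit norm. The (x, y) timeseries traces the spatial
#' trajectory of the representation.
#'
#' @param weights a features x channels x time array from
#'   [unregularized_coefficients()], or a list of such arrays (one per
#'   subject) to be RMS-combined.
#' @param layout the [sensor_layout()] the channels refer to.
#' @return tibble of class `phonseq_trajectory`: `feature`, `time` (index or
#'   seconds, see `times` attribute), `x`, `y`.
#' @param times optional time grid (s) for the output.
#' @export
project_trajectory <- function(weights, layout, times = NULL) {
  if (is.list(weights)) {
    arr <- simplify2array(weights)                    # f x c x t x subj
    W <- sqrt(apply(arr^2, c(1, 2, 3), mean))
  } else {
    W <- abs(weights)
  }
  masks <- layout_masks(layout)
  n_f <- dim(W)[1]; n_t <- dim(W)[3]
  feats <- dimnames(W)[[1]] %||% paste0("f", seq_len(n_f))
  out <- purrr::map_dfr(seq_len(n_f), function(f) {
    xs <- ys <- numeric(n_t)
    for (tt in seq_len(n_t)) {
      w <- W[f, , tt]
      nw <- sqrt(sum(w^2))
      if (nw == 0) {
        xs[tt] <- NA_real_; ys[tt] <- NA_real_       # undefined topography
      } else {
        xs[tt] <- sum(w * masks$x) / nw
        ys[tt] <- sum(w * masks$y) / nw
      }
    }
    tibble::tibble(feature = feats[f],
                   time = if (is.null(times)) seq_len(n_t) else times,
                   x = xs, y = ys)
  })
  class(out) <- c("phonseq_trajectory", class(out))
  out
}

#' Trajectory structure metric
#'
#' For each axis, `(m / s) * v` where `m` is the range of movement (max
#' minus min), `s` the mean absolute step between successive samples, and
#' `v` the standard deviation across samples; the two axes are averaged.
#' Smooth, far-ranging drifts score high; jittery or constant trajectories
#' score low (a constant trajectory scores exactly 0).
#'
#' @param traj a [project_trajectory()] tibble (any number of features).
#' @return tibble with one row per feature: `feature`, `structure`.
#' @export
trajectory_structure <- function(traj) {
  if (length(unique(traj$time)) < 10) abort("need at least 10 timepoints")
  per_axis <- function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 2) return(NA_real_)
    m <- max(z) - min(z)
    s <- mean(abs(diff(z)))
    v <- stats::sd(z)
    if (s == 0) return(0)
    (m / s) * v
  }
  traj |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(structure = mean(c(per_axis(.data$x), per_axis(.data$y))),
                     .groups = "drop")
}

#' Permutation null for trajectory structure
#'
#' Re-runs the unregularised decoding with shuffled feature labels
#' `n_perm` times, rebuilds the trajectory each time, and reports the
#' fraction of null structure metrics at least as large as the observed one
#' (reporting floor `1 / n_perm`).
#'
#' @param epochs an [epoch_set()].
#' @param Y trials x features matrix (all features refit per permutation).
#' @param layout sensor layout.
#' @param feature which feature's trajectory to test (default first column).
#' @param n_perm number of label shuffles (default 100).
#' @param seed integer seed.
#' @return list: `observed`, `null` (vector), `p`, `floor`.
#' @export
trajectory_null_test <- function(epochs, Y, layout, feature = NULL,
                                 n_perm = 100, seed = NULL) {
  Y <- as.matrix(Y)
  feature <- feature %||% colnames(Y)[1]
  obs_traj <- project_trajectory(unregularized_coefficients(epochs, Y), layout,
                                 times = epochs$times)
  obs <- trajectory_structure(obs_traj)
  obs_val <- obs$structure[obs$feature == feature]
  with_seed(seed, {
    null_vals <- vapply(seq_len(n_perm), function(p) {
      Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
      tr <- project_trajectory(unregularized_coefficients(epochs, Yp), layout,
                               times = epochs$times)
      st <- trajectory_structure(tr)
      st$structure[st$feature == feature]
    }, numeric(1))
    list(observed = obs_val, null = null_vals,
         p = mean(null_vals >= obs_val), floor = 1 / n_perm)
  })
}

#' Decode latency since phoneme onset
#'
#' Crops phoneme-locked epochs to the window of strongest phonetic decoding
#' (100-400 ms default), keeps `n_latency` equally spaced samples, collapses
#' the trial and latency dimensions so each (trial, latency) pair is one
#' observation labelled by its latency, standardises inputs and targets, and
#' fits ridge regression under shuffled k-fold cross-validation. If the
#' responses carry no latency information, held-out predictions collapse to
#' the mean training latency (250 ms for the default window).
#'
#' @param epochs an [epoch_set()].
#' @param crop latency window in seconds (default `c(0.1, 0.4)`).
#' @param n_latency number of equally spaced latency samples (default 16,
#'   i.e. an effective 53.3 Hz grid).
#' @param folds number of shuffled CV folds (default 5).
#' @param alpha ridge penalty (default 1).
#' @param seed integer seed.
#' @return object of class `phonseq_latency`: `predictions` tibble (`trial`,
#'   `latency_sample`, `true_ms`, `predicted_ms`, `fold`), overall held-out
#'   Pearson `r`, and `r_within_fold`.
#' @export
decode_latency <- function(epochs, crop = c(0.1, 0.4), n_latency = 16,
                           folds = 5, alpha = 1, seed = NULL) {
  if (crop[1] < min(epochs$times) || crop[2] > max(epochs$times)) {
    abort("crop window must lie within the epoch window")
  }
  target_t <- seq(crop[1], crop[2], length.out = n_latency)
  t_idx <- vapply(target_t, function(t) which.min(abs(epochs$times - t)), integer(1))
  lat_ms <- 1000 * epochs$times[t_idx]
  n_trials <- dim(epochs$X)[1]; n_ch <- dim(epochs$X)[2]
  n_obs <- n_trials * n_latency
  if (n_obs < 2 * folds) abort("too few observations for the requested folds")
  X <- matrix(0, n_obs, n_ch)
  y <- numeric(n_obs)
  trial_id <- integer(n_obs); samp_id <- integer(n_obs)
  row <- 1
  for (l in seq_len(n_latency)) {
    sl <- epochs$X[, , t_idx[l], drop = TRUE]
    idx <- row:(row + n_trials - 1)
    X[idx, ] <- sl
    y[idx] <- lat_ms[l]
    trial_id[idx] <- seq_len(n_trials)
    samp_id[idx] <- l
    row <- row + n_trials
  }
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), n_obs))
    pred <- numeric(n_obs)
    for (k in seq_len(folds)) {
      tr <- fold != k
      mu_x <- colMeans(X[tr, , drop = FALSE]); sd_x <- col_sds(X[tr, , drop = FALSE])
      mu_y <- mean(y[tr]); sd_y <- stats::sd(y[tr])
      fit <- ridge_solve(scale_by(X[tr, , drop = FALSE], mu_x, sd_x),
                         (y[tr] - mu_y) / sd_y, alpha = alpha)
      pz <- ridge_predict(fit, scale_by(X[!tr, , drop = FALSE], mu_x, sd_x))
      pred[!tr] <- pz * sd_y + mu_y
    }
    r <- stats::cor(y, pred)
    r_fold <- vapply(seq_len(folds), function(k) {
      stats::cor(y[fold == k], pred[fold == k])
    }, numeric(1))
    structure(list(
      predictions = tibble::tibble(trial = trial_id, latency_sample = samp_id,
                                   true_ms = y, predicted_ms = pred,
                                   fold = fold),
      r = r, r_within_fold = mean(r_fold), crop = crop,
      n_latency = n_latency, folds = folds, alpha = alpha, seed = seed),
      class = "phonseq_latency")
  })
}

#' @export
print.phonseq_latency <- function(x, ...) {
  cat(sprintf("<phonseq_latency> %d observations, held-out r = %.3f (mean prediction %.1f ms)\n",
              nrow(x$predictions), x$r, mean(x$predictions$predicted_ms)))
  invisible(x)
}
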