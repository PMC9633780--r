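# Acoustic-confound residualisation (TRF), epoching, and the mel branch.

trf_alpha_grid <- function() 10^seq(-6, 6, length.out = 10)

# Lagged design matrix: columns are regressor values at lags 0..n_lags-1
# samples in the past (each channel's activity at time t is modelled from
# the preceding window of the regressors).
lagged_design <- function(regs, n_lags) {
  n <- nrow(regs)
  out <- matrix(0, n, n_lags * ncol(regs))
  for (j in seq_len(ncol(regs))) {
    for (l in seq_len(n_lags)) {
      idx <- seq_len(n - l + 1)
      out[idx + l - 1, (j - 1) * n_lags + l] <- regs[idx, j]
    }
  }
  out
}

#' Fit a temporal receptive field (TRF) confound model
#'
#' Models each channel from the preceding 200 ms of acoustic envelope and
#' pitch estimates with ridge regression. Both regressors and recording are
#' standardised to zero mean / unit variance before fitting; the
#' regularisation strength is selected from ten log-spaced values in
#' `[1e-6, 1e+6]` by mean cross-validated predictive correlation across
#' channels over contiguous folds.
#'
#' @param recording a `phonseq_recording`, or a channels x samples matrix.
#' @param envelope,pitch regressor vectors, one value per sample (defaulted
#'   from the recording object when available).
#' @param fs sampling rate (taken from the recording object if present).
#' @param lag_window lag window in seconds (default `c(0, 0.2)`).
#' @param alphas regularisation grid.
#' @param folds number of contiguous cross-validation folds (default 3).
#' @return object of class `phonseq_trf`: selected `alpha`, per-fold
#'   coefficients, per-fold/alpha predictive scores, fold boundaries, and the
#'   standardisation statistics needed to express predictions in original
#'   recording units.
#' @export
fit_trf <- function(recording, envelope = NULL, pitch = NULL, fs = NULL,
                    lag_window = c(0, 0.2), alphas = trf_alpha_grid(),
                    folds = 3) {
  if (inherits(recording, "phonseq_recording")) {
    envelope <- envelope %||% recording$envelope
    pitch <- pitch %||% recording$pitch
    fs <- fs %||% recording$fs
    data <- recording$data
  } else {
    data <- recording
  }
  if (is.null(fs)) abort("`fs` must be supplied for matrix input")
  regs <- cbind(envelope = envelope, pitch = pitch)
  if (any(col_sds(regs) == 0)) abort("constant regressor: envelope/pitch must vary")
  if (ncol(regs) < 1 || nrow(regs) != ncol(data)) {
    abort("regressors must have one value per recording sample")
  }
  n <- nrow(regs)
  reg_mu <- colMeans(regs); reg_sd <- col_sds(regs)
  regs_z <- scale_by(regs, reg_mu, reg_sd)
  ch_mu <- rowMeans(data); ch_sd <- apply(data, 1, stats::sd)
  Yz <- t(scale_by(t(data), ch_mu, ch_sd))

  n_lags <- round(diff(lag_window) * fs) + 1
  X <- lagged_design(regs_z, n_lags)
  fold_id <- cut(seq_len(n), folds, labels = FALSE)
  p <- ncol(X)

  score <- matrix(NA_real_, length(alphas), folds)
  fold_fits <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Ytr <- t(Yz[, tr, drop = FALSE])
    XtX <- crossprod(Xtr); XtY <- crossprod(Xtr, Ytr)
    eg <- eigen(XtX, symmetric = TRUE)
    VtXtY <- crossprod(eg$vectors, XtY)
    coefs_k <- vector("list", length(alphas))
    for (a in seq_along(alphas)) {
      coef <- eg$vectors %*% (VtXtY / (eg$values + alphas[a]))
      pred <- X[te, , drop = FALSE] %*% coef
      r <- vapply(seq_len(ncol(pred)), function(j) {
        suppressWarnings(stats::cor(pred[, j], Yz[j, te]))
      }, numeric(1))
      score[a, k] <- mean(r, na.rm = TRUE)
      coefs_k[[a]] <- coef
    }
    fold_fits[[k]] <- coefs_k
  }
  mean_score <- rowMeans(score)
  best <- which.max(mean_score)
  structure(list(alpha = alphas[best], alphas = alphas, score = score,
                 mean_score = mean_score,
                 coef = lapply(fold_fits, `[[`, best),
                 fold_id = fold_id, n_lags = n_lags, fs = fs,
                 lag_window = lag_window,
                 reg_mu = reg_mu, reg_sd = reg_sd,
                 ch_mu = ch_mu, ch_sd = ch_sd,
                 regs = regs, Yz = Yz),
            class = "phonseq_trf")
}

trf_predictions <- function(trf, held_out = TRUE) {
  regs_z <- scale_by(trf$regs, trf$reg_mu, trf$reg_sd)
  X <- lagged_design(regs_z, trf$n_lags)
  n <- nrow(X)
  n_ch <- length(trf$ch_mu)
  pred_z <- matrix(0, n_ch, n)
  if (held_out) {
    for (k in seq_along(trf$coef)) {
      te <- trf$fold_id == k
      pred_z[, te] <- t(X[te, , drop = FALSE] %*% trf$coef[[k]])
    }
  } else {
    # in-sample: a single fit on all samples at the selected penalty
    full <- ridge_solve(X, t(trf$Yz), alpha = trf$alpha, intercept = FALSE)
    pred_z <- t(X %*% full$coef)
  }
  # back to original recording units
  pred_z * trf$ch_sd + trf$ch_mu
}

#' Regress the TRF-predictable signal out of a recording
#'
#' Predictions are computed per recording segment from the models fitted on
#' the other cross-validation folds (held-out predictions; set
#' `held_out = FALSE` for in-sample predictions), transformed back into
#' original recording units, and subtracted.
#'
#' @param recording the `phonseq_recording` (or matrix) the TRF was fit on.
#' @param trf a [fit_trf()] result.
#' @param held_out use held-out (default) or in-sample predictions.
#' @return recording object/matrix of residuals with the same shape.
#' @export
residualize <- function(recording, trf, held_out = TRUE) {
  data <- if (inherits(recording, "phonseq_recording")) recording$data else recording
  if (!identical(dim(data), c(length(trf$ch_mu), length(trf$fold_id)))) {
    abort("recording shape does not match the fitted TRF")
  }
  pred <- trf_predictions(trf, held_out = held_out)
  res <- data - pred
  if (inherits(recording, "phonseq_recording")) {
    recording$data <- res
    recording$trf_prediction <- pred
    recording
  } else {
    res
  }
}

# Zero-phase band-pass via the frequency domain with raised-cosine
# transition bands (10% of each cutoff). Robust for arbitrary recording
# lengths, including cutoffs far below 1 Hz.
fft_bandpass <- function(x, fs, highpass = 0.1, lowpass = 50) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)            # two-sided
  gain <- rep(1, n)
  if (!is.null(lowpass) && lowpass > 0) {
    tw <- 0.1 * lowpass
    gain <- gain * stats::plogis(-(freqs - lowpass) / (tw / 6))
  }
  if (!is.null(highpass) && highpass > 0) {
    tw <- 0.1 * highpass
    gain <- gain * stats::plogis((freqs - highpass) / (tw / 6))
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Epoch a continuous recording around phoneme onsets
#'
#' The recording is zero-phase band-pass filtered (0.1-50 Hz default, i.e.
#' band-limited below the decimated Nyquist), decimated to `fs_out`, and cut
#' into fixed windows around each onset (-200..600 ms default, 201 samples at
#' 250 Hz). Events whose window extends past the recording edge are dropped
#' and reported. No baseline correction is applied.
#'
#' @param recording a `phonseq_recording` or channels x samples matrix.
#' @param onsets event onsets in seconds (defaulted from the recording's
#'   events when available).
#' @param fs input sampling rate (from the recording object if present).
#' @param fs_out output sampling rate (default 250 Hz).
#' @param window epoch window in seconds (default `c(-0.2, 0.6)`).
#' @param highpass,lowpass band edges in Hz (`NULL` disables one side).
#' @param layout sensor layout (from the recording object if present).
#' @return an [epoch_set()]; attribute `"dropped"` holds the indices of
#'   dropped events, and `annotation_index` maps trials to event rows.
#' @export
epoch_events <- function(recording, onsets = NULL, fs = NULL, fs_out = 250,
                         window = c(-0.2, 0.6), highpass = 0.1, lowpass = 50,
                         layout = NULL) {
  if (inherits(recording, "phonseq_recording")) {
    onsets <- onsets %||% recording$events$onset
    fs <- fs %||% recording$fs
    layout <- layout %||% recording$layout
    data <- recording$data
  } else {
    data <- recording
  }
  if (is.null(fs)) abort("`fs` must be supplied for matrix input")
  if (is.null(layout)) layout <- sensor_layout(nrow(data))
  dec <- round(fs / fs_out)
  if (abs(fs / fs_out - dec) > 1e-9) abort("fs must be an integer multiple of fs_out")
  if (!is.null(lowpass) && lowpass >= fs_out / 2) {
    warn("lowpass at or above the decimated Nyquist; spectra will alias")
  }
  filt <- t(apply(data, 1, fft_bandpass, fs = fs, highpass = highpass,
                  lowpass = lowpass))
  ds <- filt[, seq(1, ncol(filt), by = dec), drop = FALSE]
  times <- seq(window[1], window[2], by = 1 / fs_out)
  rel_idx <- round(times * fs_out)
  n_t <- length(times)
  onset_idx <- round(onsets * fs_out) + 1
  lo <- onset_idx + rel_idx[1]
  hi <- onset_idx + rel_idx[n_t]
  ok <- lo >= 1 & hi <= ncol(ds)
  if (!any(ok)) abort("no valid events: all epochs extend past the recording edge")
  dropped <- which(!ok)
  if (length(dropped)) {
    inform(sprintf("dropped %d event(s) too close to the recording edge",
                   length(dropped)))
  }
  keep <- which(ok)
  X <- array(0, dim = c(length(keep), nrow(ds), n_t))
  for (i in seq_along(keep)) {
    X[i, , ] <- ds[, (onset_idx[keep[i]] + rel_idx[1]):(onset_idx[keep[i]] + rel_idx[n_t])]
  }
  out <- epoch_set(X, times, layout, annotation_index = keep)
  attr(out, "dropped") <- dropped
  out
}

#' Mel-spectrogram front end
#'
#' Power in mel-spaced triangular bands (208 by default, analogous to a
#' 208-channel sensor array), from a short-time Fourier transform with a
#' 2048-sample Hamming window and 128 samples shared between successive
#' frames (hop = 2048 - 128), linearly resampled to `fs_out`.
#'
#' @param wave numeric mono waveform.
#' @param fs audio sampling rate in Hz.
#' @param n_bands number of mel bands (default 208).
#' @param fmin,fmax filterbank range in Hz (default 1-11250; capped at the
#'   Nyquist frequency).
#' @param n_fft analysis window length (default 2048).
#' @param overlap samples shared between successive frames (default 128).
#' @param fs_out output frame rate in Hz (default 250).
#' @return list with `power` (bands x frames), `times`, `fs_out`,
#'   `band_centers_hz`.
#' @export
mel_branch <- function(wave, fs, n_bands = 208, fmin = 1, fmax = 11250,
                       n_fft = 2048, overlap = 128, fs_out = 250) {
  if (length(wave) == 0) abort("empty audio")
  if (length(wave) < n_fft) abort("audio shorter than one analysis window")
  fmax <- min(fmax, fs / 2)
  sp <- signal::specgram(wave, n = n_fft, Fs = fs,
                         window = signal::hamming(n_fft), overlap = overlap)
  pow <- abs(sp$S)^2                        # freq x frames
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  mpts <- mel2hz(seq(hz2mel(fmin), hz2mel(fmax), length.out = n_bands + 2))
  fb <- matrix(0, n_bands, length(sp$f))
  for (b in seq_len(n_bands)) {
    lo <- mpts[b]; ce <- mpts[b + 1]; hi <- mpts[b + 2]
    up <- (sp$f - lo) / (ce - lo)
    down <- (hi - sp$f) / (hi - ce)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  mel_pow <- fb %*% pow                     # bands x frames
  frame_t <- sp$t
  t_out <- seq(min(frame_t), max(frame_t), by = 1 / fs_out)
  out <- t(apply(mel_pow, 1, function(p) {
    stats::approx(frame_t, p, xout = t_out, rule = 2)$y
  }))
  list(power = out, times = t_out, fs_out = fs_out,
       band_centers_hz = mpts[2:(n_bands + 1)])
}
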