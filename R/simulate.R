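# Synthetic test bed: phoneme streams and multichannel recordings with
# planted feature codes.
#
# The generator emulates the essential structure of phoneme-locked speech
# recordings: ~78 ms phonemes whose evoked responses last ~300 ms and overlap
# linearly; binary phonetic features carried by channel topographies that are
# either fixed over latency (static code) or rotate smoothly with time since
# onset (dynamic code); acoustic envelope/pitch confounds; and white sensor
# noise at configurable SNR.

#' Sensor layout on the unit disc
#'
#' Channels are placed on a sunflower spiral covering the unit disc, giving
#' roughly uniform density and well-defined anterior/posterior (y) and
#' left/right (x) halves for trajectory masks.
#'
#' @param n_channels number of channels (default 208, matching a 208-channel
#'   axial gradiometer array).
#' @return tibble with columns `channel`, `x`, `y`.
#' @export
sensor_layout <- function(n_channels = 208) {
  if (n_channels < 2) abort("`n_channels` must be at least 2")
  k <- seq_len(n_channels)
  r <- sqrt((k - 0.5) / n_channels)
  theta <- k * pi * (3 - sqrt(5))
  tibble::tibble(channel = k, x = r * cos(theta), y = r * sin(theta))
}

#' Simulation configuration
#'
#' Defaults encode the study conditions of the synthetic test bed: 1000 Hz
#' raw / 250 Hz epoch sampling, phoneme durations from a truncated normal
#' (mean 78 ms, SD 34 ms, > 20 ms), a 0-300 ms response window, and
#' inter-word / inter-sentence silences drawn uniformly from `[0, max]`.
#'
#' @param fs_raw raw sampling rate in Hz.
#' @param fs_epoch epoch sampling rate in Hz.
#' @param snr signal-to-noise amplitude ratio (RMS of the planted signal
#'   divided by the white-noise SD); `0` means noise only, `Inf` noise-free.
#' @param duration_mean,duration_sd,duration_min phoneme duration
#'   distribution in seconds (truncated normal).
#' @param word_gap_max,sentence_gap_max upper bounds (s) of the uniform
#'   silence distributions between words and sentences.
#' @param confound_gain_envelope,confound_gain_pitch amplitude of the
#'   acoustic confound components relative to the planted code RMS.
#' @param response_window response window in seconds since phoneme onset.
#' @param ar1 optional AR(1) coefficient for temporally correlated sensor
#'   noise (0 = white, the default).
#' @return a list of class `phonseq_sim_config`.
#' @export
sim_config <- function(fs_raw = 1000, fs_epoch = 250, snr = 1,
                       duration_mean = 0.078, duration_sd = 0.034,
                       duration_min = 0.02, word_gap_max = 0.02,
                       sentence_gap_max = 1.0,
                       confound_gain_envelope = 0, confound_gain_pitch = 0,
                       response_window = c(0, 0.3), ar1 = 0) {
  for (nm in c("fs_raw", "fs_epoch", "duration_mean", "duration_sd")) {
    stopifnot_scalar_count(get(nm), nm)
  }
  cfg <- list(fs_raw = fs_raw, fs_epoch = fs_epoch, snr = snr,
              duration_mean = duration_mean, duration_sd = duration_sd,
              duration_min = duration_min, word_gap_max = word_gap_max,
              sentence_gap_max = sentence_gap_max,
              confound_gain_envelope = confound_gain_envelope,
              confound_gain_pitch = confound_gain_pitch,
              response_window = response_window, ar1 = ar1)
  class(cfg) <- "phonseq_sim_config"
  cfg
}

#' Simulation presets
#'
#' * `"clean"`: dynamic code, high SNR -- every downstream stage recovers its
#'   planted structure comfortably.
#' * `"paper-like"`: dynamic code at low SNR, chosen so that single-feature
#'   AUC decoding lands only a point or two above chance, the regime the
#'   method is designed for.
#' * `"static-control"`: static code (no drift), high SNR -- the control
#'   condition whose temporal-generalisation matrix is square.
#'
#' @param name preset name.
#' @return list with elements `config` (a [sim_config()]) and `drift_rate`
#'   (rotation cycles per second of latency).
#' @export
sim_preset <- function(name = c("clean", "paper-like", "static-control")) {
  name <- match.arg(name)
  switch(name,
    "clean" = list(config = sim_config(snr = 3), drift_rate = 6.25),
    "paper-like" = list(config = sim_config(snr = 0.004), drift_rate = 6.25),
    "static-control" = list(config = sim_config(snr = 3), drift_rate = 0))
}

#' Sample a phoneme stream from a lexicon
#'
#' Words are drawn with probability proportional to lexicon frequency and
#' grouped into sentences; phoneme durations come from the configured
#' truncated normal; silences between words and sentences are uniform on
#' `[0, max]`.
#'
#' @param lex a [lexicon()].
#' @param n_words number of word tokens to sample.
#' @param config a [sim_config()].
#' @param seed integer seed (optional).
#' @param words_per_sentence integer range for sentence lengths.
#' @return events tibble (`label`, `onset`, `duration`, `word`, `word_id`,
#'   `sentence_id`) ready for [annotate_stream()].
#' @export
sample_stream <- function(lex, n_words, config = sim_config(), seed = NULL,
                          words_per_sentence = c(5, 12)) {
  stopifnot_scalar_count(n_words, "n_words")
  if (nrow(lex) == 0) abort("lexicon is empty")
  with_seed(seed, {
    widx <- sample.int(nrow(lex), n_words, replace = TRUE,
                       prob = lex$frequency / sum(lex$frequency))
    sent_len <- sample(seq(words_per_sentence[1], words_per_sentence[2]),
                       n_words, replace = TRUE)
    sent_id <- rep(seq_along(sent_len), times = sent_len)[seq_len(n_words)]
    rows <- vector("list", n_words)
    t <- 0
    for (i in seq_len(n_words)) {
      labs <- split_phonemes(lex$phonemes[widx[i]])[[1]]
      durs <- rtnorm_lower(length(labs), config$duration_mean,
                           config$duration_sd, config$duration_min)
      onsets <- t + cumsum(c(0, durs[-length(durs)]))
      rows[[i]] <- tibble::tibble(label = labs, onset = onsets, duration = durs,
                                  word = lex$word[widx[i]], word_id = i,
                                  sentence_id = sent_id[i])
      t <- onsets[length(onsets)] + durs[length(durs)]
      gap_max <- if (i < n_words && sent_id[i + 1] != sent_id[i]) {
        config$sentence_gap_max
      } else {
        config$word_gap_max
      }
      t <- t + stats::runif(1, 0, gap_max)
    }
    dplyr::bind_rows(rows)
  })
}

#' Plant a static or dynamic feature code
#'
#' Each feature receives a random unit-norm channel pattern. With
#' `drift_rate > 0` the pattern rotates smoothly through channel space as
#' latency since phoneme onset increases: the pattern follows a piecewise
#' geodesic through a sequence of random orthonormal directions (a cascade of
#' Givens rotations, each within the plane spanned by two successive
#' waypoints) at a constant angular rate of `2 * pi * drift_rate` radians per
#' second. The correlation between the pattern at latency 0 and latency `t`
#' therefore falls off as `cos(2 * pi * drift_rate * t)` until orthogonality
#' and stays at zero afterwards, so a training pattern is informative over a
#' total width of `1 / (2 * drift_rate)` seconds: `drift_rate = 6.25` gives
#' the 80 ms informative width of the dynamic presets. `drift_rate = 0` yields a static code (identical pattern at
#' every latency, emulating the stationary cues of the acoustic signal).
#'
#' Response amplitude follows a half-cosine rising/falling envelope over the
#' response window.
#'
#' @param layout a [sensor_layout()].
#' @param feature_names names of the planted features.
#' @param drift_rate pattern rotation in cycles per second of latency
#'   (non-negative).
#' @param seed integer seed.
#' @param window response window in seconds (default `c(0, 0.3)`).
#' @param fs latency sampling rate of the stored code (default 250 Hz).
#' @param envelope amplitude envelope over the response window:
#'   `"halfcos"` (default) or `"boxcar"` (flat; a static boxcar code is a
#'   truly stationary pattern with no amplitude cue to latency).
#' @param duration_scaled if `TRUE`, the drift clock runs in units of the
#'   eliciting phoneme's duration relative to `ref_duration` instead of wall
#'   clock time (long phonemes drift more slowly).
#' @param ref_duration reference duration (s) for `duration_scaled`.
#' @return object of class `phonseq_code`: list with `W` (feature x channel x
#'   latency array of unit-norm patterns), `envelope`, `latencies`, plus the
#'   generating parameters.
#' @export
make_code <- function(layout, feature_names, drift_rate = 0, seed = NULL,
                      window = c(0, 0.3), fs = 250, duration_scaled = FALSE,
                      ref_duration = 0.078,
                      envelope = c("halfcos", "boxcar")) {
  envelope <- match.arg(envelope)
  if (drift_rate < 0) abort("`drift_rate` must be non-negative")
  n_ch <- nrow(layout)
  n_f <- length(feature_names)
  if (n_ch < n_f) abort("fewer channels than features")
  lat <- seq(window[1], window[2], by = 1 / fs)
  L <- length(lat)
  with_seed(seed, {
    W <- array(0, dim = c(n_f, n_ch, L),
               dimnames = list(feature_names, NULL, NULL))
    phi <- 2 * pi * drift_rate * (lat - lat[1])      # accumulated angle
    n_seg <- max(1L, ceiling(max(phi) / (pi / 2)))
    if (drift_rate > 0 && n_ch < n_seg + 1) {
      abort("too few channels for the requested drift schedule")
    }
    for (f in seq_len(n_f)) {
      # orthonormal waypoint directions q_0 (the base pattern), q_1, ...
      Q <- matrix(stats::rnorm(n_ch * (n_seg + 1)), n_ch)
      Q[, 1] <- Q[, 1] / sqrt(sum(Q[, 1]^2))
      if (n_seg >= 1 && drift_rate > 0) {
        for (j in 2:(n_seg + 1)) {
          v <- Q[, j]
          v <- v - Q[, 1:(j - 1), drop = FALSE] %*%
            crossprod(Q[, 1:(j - 1), drop = FALSE], v)
          Q[, j] <- v / sqrt(sum(v^2))
        }
      }
      for (l in seq_len(L)) {
        if (drift_rate == 0) {
          W[f, , l] <- Q[, 1]
        } else {
          k <- min(floor(phi[l] / (pi / 2)), n_seg - 1)
          a <- phi[l] - k * pi / 2
          W[f, , l] <- cos(a) * Q[, k + 1] + sin(a) * Q[, k + 2]
        }
      }
    }
    env <- if (envelope == "boxcar") rep(1, L) else {
      sin(pi * seq(0, 1, length.out = L))        # half-cosine rise/fall
    }
    out <- list(W = W, envelope = env, latencies = lat,
                feature_names = feature_names, drift_rate = drift_rate,
                fs = fs, layout = layout, duration_scaled = duration_scaled,
                ref_duration = ref_duration, seed = seed)
    class(out) <- "phonseq_code"
    out
  })
}

# Pattern (channel vector, envelope applied) of feature f at latency index l,
# optionally under a duration-scaled drift clock.
code_pattern <- function(code, f, l, duration = NULL) {
  L <- dim(code$W)[3]
  l_eff <- l
  if (isTRUE(code$duration_scaled) && !is.null(duration)) {
    l_eff <- round((l - 1) * code$ref_duration / duration) + 1
    l_eff <- min(max(l_eff, 1L), L)
  }
  code$envelope[l] * code$W[f, , l_eff]
}

# Smooth acoustic-envelope regressor: boxcars over phoneme extents convolved
# with a short raised-cosine kernel.
acoustic_envelope <- function(events, n_samples, fs) {
  env <- numeric(n_samples)
  for (i in seq_len(nrow(events))) {
    a <- floor(events$onset[i] * fs) + 1
    b <- min(n_samples, a + max(1, round(events$duration[i] * fs)) - 1)
    if (a <= n_samples) env[a:b] <- env[a:b] + 1
  }
  k <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = round(0.02 * fs) + 2)))
  as.numeric(stats::filter(env, k / sum(k), sides = 2)) -> sm
  sm[is.na(sm)] <- 0
  sm
}

# Smooth pitch-proxy regressor: low-pass filtered random walk, z-scored.
pitch_proxy <- function(n_samples, fs) {
  x <- cumsum(stats::rnorm(n_samples))
  k <- rep(1, max(2, round(0.05 * fs)))
  sm <- as.numeric(stats::filter(x, k / sum(k), sides = 2))
  sm[is.na(sm)] <- 0
  zscore(sm)
}

simulate_core <- function(events, annotation, code, config, seed,
                          active_mode = c("response", "acoustic")) {
  active_mode <- match.arg(active_mode)
  fs <- config$fs_raw
  feature_names <- code$feature_names
  # "onset" is a generic evoked component shared by every phoneme (value 1);
  # all other planted features must be annotation columns
  miss <- setdiff(setdiff(feature_names, "onset"), names(annotation))
  if (length(miss)) abort(paste("annotation lacks planted feature column(s):",
                                paste(miss, collapse = ", ")))
  if (nrow(annotation) != nrow(events)) abort("annotation does not match events")
  n_ch <- dim(code$W)[2]
  L <- dim(code$W)[3]
  lat_step <- round(fs / code$fs)          # raw samples per stored latency step
  t_end <- max(events$onset + events$duration) + max(code$latencies) + 0.2
  n_samples <- ceiling(t_end * fs)
  Yp <- vapply(feature_names, function(f) {
    if (f == "onset" && !f %in% names(annotation)) rep(1, nrow(events))
    else annotation[[f]]
  }, numeric(nrow(events)))
  Yp <- matrix(Yp, nrow = nrow(events), dimnames = list(NULL, feature_names))

  with_seed(seed, {
    sig <- matrix(0, n_ch, n_samples)
    for (i in seq_len(nrow(events))) {
      s0 <- floor(events$onset[i] * fs) + 1
      if (active_mode == "acoustic") {
        L_i <- max(1L, min(L, round(events$duration[i] * code$fs)))
      } else {
        L_i <- L
      }
      for (l in seq_len(L_i)) {
        s <- s0 + (l - 1) * lat_step
        if (s > n_samples) break
        s_hi <- min(s + lat_step - 1, n_samples)
        for (f in seq_along(feature_names)) {
          y <- Yp[i, f]
          if (y == 0) next
          pat <- if (active_mode == "acoustic") {
            code$W[f, , 1]                 # static, unit envelope while active
          } else {
            code_pattern(code, f, l, events$duration[i])
          }
          sig[, s:s_hi] <- sig[, s:s_hi] + y * pat
        }
      }
    }
    env <- acoustic_envelope(events, n_samples, fs)
    pit <- pitch_proxy(n_samples, fs)
    sig_rms <- sqrt(mean(sig^2))
    if (sig_rms == 0) sig_rms <- 1
    if (config$confound_gain_envelope > 0) {
      pat <- stats::rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
      sig <- sig + config$confound_gain_envelope * sig_rms *
        pat %o% zscore(env)
    }
    if (config$confound_gain_pitch > 0) {
      pat <- stats::rnorm(n_ch); pat <- pat / sqrt(sum(pat^2))
      sig <- sig + config$confound_gain_pitch * sig_rms * pat %o% pit
    }
    if (is.infinite(config$snr)) {
      data <- sig
    } else if (config$snr > 0) {
      noise_sd <- sqrt(mean(sig^2)) / config$snr
      data <- sig + matrix(stats::rnorm(length(sig), sd = noise_sd), n_ch)
    } else {
      data <- matrix(stats::rnorm(n_ch * n_samples), n_ch)
    }
    if (config$ar1 > 0) {
      data <- t(apply(data, 1, function(x) {
        as.numeric(stats::filter(x, config$ar1, method = "recursive"))
      }))
    }
    out <- list(data = data, fs = fs, n_samples = n_samples,
                envelope = env, pitch = pit, events = events,
                layout = code$layout, seed = seed, config = config)
    class(out) <- "phonseq_recording"
    out
  })
}

#' Simulate a continuous multichannel recording
#'
#' Each phoneme event contributes the planted code patterns weighted by its
#' feature values, placed at its onset; responses of neighbouring phonemes
#' sum linearly (superposition); acoustic envelope/pitch confounds are
#' injected with the configured gains; white sensor noise is added at the
#' configured SNR.
#'
#' @param events events tibble from [sample_stream()].
#' @param annotation matching [annotate_stream()] table (or any tibble with
#'   the planted feature columns).
#' @param code a [make_code()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `phonseq_recording`: `data` (channels x samples),
#'   `fs`, confound regressors `envelope` and `pitch`, `events`, `layout`.
#' @export
#' @param duration optional total recording duration in seconds; events
#'   extending past it raise an error.
simulate_recording <- function(events, annotation, code,
                               config = sim_config(), seed = NULL,
                               duration = NULL) {
  if (any(events$onset < 0)) abort("events must start at non-negative times")
  if (!is.null(duration) &&
      max(events$onset + events$duration) > duration) {
    abort("events extend past the requested recording duration")
  }
  simulate_core(events, annotation, code, config, seed, "response")
}

#' Simulate the acoustic (pseudo-spectrogram) branch
#'
#' As [simulate_recording()], but the code is static (drift forced to zero by
#' construction) and each feature is active only during its phoneme's
#' acoustic extent, emulating the stationary short-lived cues of a
#' spectrogram. Channels play the role of frequency bands.
#'
#' @inheritParams simulate_recording
#' @param n_bands number of pseudo-spectrogram bands.
#' @return a `phonseq_recording` whose channels are bands.
#' @export
simulate_audio_branch <- function(events, annotation, config = sim_config(),
                                  seed = NULL, n_bands = 208) {
  code <- make_code(sensor_layout(n_bands),
                    feature_names = intersect(phonetic_feature_names(),
                                              names(annotation)),
                    drift_rate = 0, seed = child_seed(seed, 77),
                    fs = config$fs_epoch)
  simulate_core(events, annotation, code, config, seed, "acoustic")
}

#' Simulate phoneme-locked epochs directly
#'
#' Convenience generator for isolated (non-overlapping) trials: each trial is
#' the planted response for its feature row plus sensor noise, sampled on the
#' standard epoch grid. Used throughout the test bed where overlap between
#' neighbouring phonemes is not the object of study.
#'
#' @param Y numeric matrix or tibble (trials x planted features), +/-1 coded.
#' @param code a [make_code()].
#' @param snr signal-to-noise amplitude ratio; `0` gives pure noise epochs.
#' @param seed integer seed.
#' @param times epoch time grid in seconds (default -0.2..0.6 at 250 Hz,
#'   201 samples).
#' @param durations optional per-trial phoneme durations (s), used by
#'   duration-scaled codes.
#' @return an [epoch_set()].
#' @export
simulate_epochs <- function(Y, code, snr = 1, seed = NULL,
                            times = seq(-0.2, 0.6, by = 0.004),
                            durations = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) != dim(code$W)[1]) {
    abort("Y must have one column per planted code feature")
  }
  n_trials <- nrow(Y)
  n_ch <- dim(code$W)[2]
  n_t <- length(times)
  L <- dim(code$W)[3]
  lat_idx <- match(round(times * code$fs), round(code$latencies * code$fs))
  with_seed(seed, {
    X <- array(0, dim = c(n_trials, n_ch, n_t))
    if (is.null(durations) || !isTRUE(code$duration_scaled)) {
      # fast path: one channel x time template per feature
      for (f in seq_len(ncol(Y))) {
        tmpl <- matrix(0, n_ch, n_t)
        for (tt in seq_len(n_t)) {
          l <- lat_idx[tt]
          if (!is.na(l)) tmpl[, tt] <- code$envelope[l] * code$W[f, , l]
        }
        X <- X + outer(Y[, f], tmpl)       # trials x channels x time
      }
    } else {
      for (i in seq_len(n_trials)) {
        tr <- matrix(0, n_ch, n_t)
        for (tt in seq_len(n_t)) {
          l <- lat_idx[tt]
          if (is.na(l)) next
          for (f in seq_len(ncol(Y))) {
            if (Y[i, f] == 0) next
            tr[, tt] <- tr[, tt] + Y[i, f] * code_pattern(code, f, l, durations[i])
          }
        }
        X[i, , ] <- tr
      }
    }
    sig_rms <- sqrt(mean(X^2))
    if (is.infinite(snr)) {
      # noise-free
    } else if (snr > 0 && sig_rms > 0) {
      X <- X + array(stats::rnorm(length(X), sd = sig_rms / snr), dim = dim(X))
    } else {
      X <- array(stats::rnorm(length(X)), dim = dim(X))
    }
    epoch_set(X, times, code$layout, seed = seed)
  })
}
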