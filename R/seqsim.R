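# Anagram sequence-reconstruction simulation: how many previous phonemes can
# be read out from an instantaneous response when evoked responses overlap?

#' Enumerate anagram sequences of a phoneme set
#'
#' All orderings without repetition, lexicographically sorted for
#' determinism.
#'
#' @param phonemes character vector of distinct phonemes (default
#'   `c("b", "p", "s", "z")`).
#' @return character vector of `factorial(length(phonemes))` collapsed
#'   sequences (e.g. `"bpsz"`).
#' @export
enumerate_anagrams <- function(phonemes = c("b", "p", "s", "z")) {
  if (anyDuplicated(phonemes)) abort("phonemes must be distinct")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  sort(vapply(perms(sort(phonemes)), paste, character(1), collapse = ""))
}

# Default +/-1 voicing/plosive feature coding for the anagram phoneme set.
anagram_features <- function(phonemes) {
  ft <- build_feature_table(phonemes)
  cbind(voicing = pm1(ft$voicing[match(phonemes, ft$phoneme)]),
        plosive = pm1(ft$plosive[match(phonemes, ft$phoneme)]))
}

#' Synthesise responses to phoneme anagram sequences
#'
#' Each phoneme's response is the sum of its feature values times the
#' corresponding spatiotemporal coefficient template, multiplied by a
#' per-occurrence noise factor, placed at `k * shift_ms` for sequence
#' position `k`, and summed over the overlapping sequence (linear
#' superposition). The sequences of one repetition are concatenated
#' back-to-back in a freshly shuffled order with a constant `shift_ms`
#' phoneme rate, so that history lags beyond one sequence reach into an
#' unpredictable previous sequence.
#'
#' @param anagrams character vector from [enumerate_anagrams()].
#' @param coefficients a [make_code()] object whose features cover the
#'   phoneme features (default features: voicing, plosive), or a feature x
#'   channel x latency array with named features.
#' @param shift_ms inter-phoneme shift (default 100 ms).
#' @param n_repetitions responses per sequence (default 10).
#' @param noise_sd SD of the multiplicative Gaussian noise factor
#'   (mean 1; `0` disables noise so repetitions are identical).
#' @param seed integer seed.
#' @param fs sampling rate of the templates (taken from a code object).
#' @return list of class `phonseq_seqsim_data`: `data` (list of channel x
#'   time matrices, one per repetition stream), `events` tibble (`rep`,
#'   `seq`, `pos`, `label`, `onset_s`), true feature matrix `Y`, `fs`,
#'   template metadata.
#' @export
synthesize_sequence_responses <- function(anagrams, coefficients,
                                          shift_ms = 100, n_repetitions = 10,
                                          noise_sd = 0.1, seed = NULL,
                                          fs = NULL) {
  if (inherits(coefficients, "phonseq_code")) {
    fs <- fs %||% coefficients$fs
    feats <- coefficients$feature_names
    L <- dim(coefficients$W)[3]
    tmpl <- lapply(seq_along(feats), function(f) {
      sweep(coefficients$W[f, , , drop = TRUE], 2, coefficients$envelope, "*")
    })
  } else {
    if (is.null(fs)) abort("`fs` must be supplied for array templates")
    feats <- dimnames(coefficients)[[1]]
    if (is.null(feats)) abort("array templates must have named features")
    L <- dim(coefficients)[3]
    tmpl <- lapply(seq_along(feats), function(f) coefficients[f, , , drop = TRUE])
  }
  names(tmpl) <- feats
  phon <- sort(unique(unlist(strsplit(anagrams, ""))))
  Yp <- anagram_features(phon)
  miss <- setdiff(c("voicing", "plosive"), feats)
  if (length(miss)) {
    abort(paste("coefficient templates lack feature(s):", paste(miss, collapse = ", ")))
  }
  use_feats <- intersect(feats, colnames(Yp))
  n_ch <- nrow(tmpl[[1]])
  shift <- round(shift_ms / 1000 * fs)
  seq_len_ph <- nchar(anagrams[1])
  n_onsets <- length(anagrams) * seq_len_ph
  with_seed(seed, {
    events <- list(); data <- vector("list", n_repetitions)
    for (r in seq_len(n_repetitions)) {
      n_samp <- n_onsets * shift + L + shift
      canvas <- matrix(0, n_ch, n_samp)
      pos_global <- 0
      ev <- vector("list", n_onsets)
      seq_order <- sample(anagrams)     # fresh presentation order per stream
      for (si in seq_along(seq_order)) {
        labs <- strsplit(seq_order[si], "")[[1]]
        for (k in seq_along(labs)) {
          s0 <- pos_global * shift + 1
          span <- s0:(s0 + L - 1)
          for (f in use_feats) {
            yv <- Yp[match(labs[k], phon), f]
            nf <- if (noise_sd > 0) stats::rnorm(1, 1, noise_sd) else 1
            canvas[, span] <- canvas[, span] + yv * nf * tmpl[[f]]
          }
          ev[[pos_global + 1]] <- tibble::tibble(
            rep = r, seq = seq_order[si], pos = k, label = labs[k],
            onset_s = (s0 - 1) / fs)
          pos_global <- pos_global + 1
        }
      }
      data[[r]] <- canvas
      events[[r]] <- dplyr::bind_rows(ev)
    }
    events <- dplyr::bind_rows(events)
    Y <- Yp[match(events$label, phon), use_feats, drop = FALSE]
    structure(list(data = data, events = events, Y = Y, fs = fs,
                   shift_ms = shift_ms, template_length = L,
                   features = use_feats, phonemes = phon, seed = seed),
              class = "phonseq_seqsim_data")
  })
}

#' Reconstruct phoneme history from overlapping responses
#'
#' Epochs are extracted around each phoneme onset; ridge regression (small
#' fixed penalty, shuffled k-fold cross-validation) predicts the feature
#' vector of the phoneme `lag - 1` steps back from each epoch (lag 1 = the
#' current phoneme). Accuracy per lag is the cosine similarity between the
#' concatenated true and reconstructed feature vectors; significance comes
#' from a label-shuffling permutation null.
#'
#' @param responses a [synthesize_sequence_responses()] result.
#' @param max_history largest lag (default 6; lags reaching before the
#'   start of a repetition stream are evaluated on the available epochs).
#' @param window epoch window in seconds after onset (default the template
#'   length).
#' @param alpha fixed ridge penalty (default 1e-6).
#' @param folds shuffled CV folds (default 5).
#' @param n_perm permutations for the null (default 10000).
#' @param seed integer seed.
#' @return tibble of class `phonseq_seqsim`: `lag`, `similarity`, `p`,
#'   `n_epochs`.
#' @export
reconstruct_history <- function(responses, max_history = 6, window = NULL,
                                alpha = 1e-6, folds = 5, n_perm = 10000,
                                seed = NULL) {
  fs <- responses$fs
  L <- responses$template_length
  win_len <- if (is.null(window)) L else round(diff(window) * fs) + 1
  ev <- responses$events
  n_ev <- nrow(ev)
  n_ch <- nrow(responses$data[[1]])
  X <- matrix(0, n_ev, n_ch * win_len)
  for (i in seq_len(n_ev)) {
    s0 <- round(ev$onset_s[i] * fs) + 1
    X[i, ] <- as.vector(responses$data[[ev$rep[i]]][, s0:(s0 + win_len - 1)])
  }
  Y <- as.matrix(responses$Y)
  # index of each epoch within its repetition stream
  within <- stats::ave(seq_len(n_ev), ev$rep, FUN = seq_along)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(max_history), function(lag) {
      back <- lag - 1L
      ok <- within > back
      tgt_idx <- seq_len(n_ev) - back
      Xl <- X[ok, , drop = FALSE]
      Yl <- Y[tgt_idx[ok], , drop = FALSE]
      n <- nrow(Xl)
      fold <- sample(rep_len(seq_len(folds), n))
      pred <- matrix(0, n, ncol(Yl))
      for (k in seq_len(folds)) {
        tr <- fold != k
        fit <- ridge_solve(Xl[tr, , drop = FALSE], Yl[tr, , drop = FALSE],
                           alpha = alpha)
        pred[!tr, ] <- ridge_predict(fit, Xl[!tr, , drop = FALSE])
      }
      obs <- cosine_sim(as.vector(Yl), as.vector(pred))
      null <- vapply(seq_len(n_perm), function(p) {
        cosine_sim(as.vector(Yl[sample.int(n), , drop = FALSE]), as.vector(pred))
      }, numeric(1))
      tibble::tibble(lag = lag, similarity = obs,
                     p = max(mean(null >= obs), 1 / n_perm), n_epochs = n)
    })
    class(out) <- c("phonseq_seqsim", class(out))
    out
  })
}
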