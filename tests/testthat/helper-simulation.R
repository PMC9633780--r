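# Shared synthetic fixtures. Expensive objects are memoised so several test
# files (and the acceptance blocks) can reuse one computation per session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

# Concatenate two epoch sets along the trial axis.
cat_epochs <- function(e1, e2) {
  n1 <- dim(e1$X)[1]; n2 <- dim(e2$X)[1]
  X <- array(0, dim = c(n1 + n2, dim(e1$X)[2], dim(e1$X)[3]))
  X[seq_len(n1), , ] <- e1$X
  X[n1 + seq_len(n2), , ] <- e2$X
  epoch_set(X, e1$times, e1$layout)
}

# Coarse 50 Hz analysis grid spanning the standard epoch window.
coarse_times <- seq(-0.2, 0.6, by = 0.02)

# Random +/-1 feature matrix.
rand_pm1 <- function(n, cols, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(c(-1, 1), n * length(cols), replace = TRUE), n)
    colnames(m) <- cols
    m
  })
}

# Group-level TG t-maps for matched static and dynamic codes: 6 simulated
# subjects each, 120 trials, 24 channels, SNR 0.5, 3 splits on the coarse
# grid. Used for the square-vs-diagonal, overlap and ridge-angle checks.
fx_tg_maps <- function() {
  fx("tg_maps", function() {
    lay <- sensor_layout(24)
    one_subject <- function(drift, s) {
      code <- make_code(lay, c("voicing", "plosive"), drift_rate = drift,
                        seed = 2, fs = 50)
      Y <- rand_pm1(120, c("voicing", "plosive"), seed = 100 + s)
      ep <- simulate_epochs(Y, code, snr = 0.5, seed = 200 + s,
                            times = coarse_times)
      tg_fit_eval(ep, Y, n_splits = 3, seed = 300 + s)
    }
    list(
      static = tg_tmap(lapply(1:6, function(s) one_subject(0, s))),
      dynamic = tg_tmap(lapply(1:6, function(s) one_subject(6.25, s + 50)))
    )
  })
}

# Word-clock aligned copies of one t-map for positions P1..P5 (a
# position-invariant code produces the same surface at every position).
fx_positions <- function(tm, step_ms = 80) {
  l <- stats::setNames(lapply(1:5, function(k) tm), paste0("P", 1:5))
  align_to_word_clock(l, step_ms = step_ms)$tg
}

# B2B selectivity fixture: per-"subject" betas for a planted feature and a
# correlated (r ~ 0.7) covariate that is not planted.
fx_selectivity <- function() {
  fx("selectivity", function() {
    lay <- sensor_layout(24)
    code <- make_code(lay, "f", drift_rate = 0, seed = 3)
    betas <- vapply(1:8, function(s) {
      withr::with_seed(s, {
        f <- sample(c(-1, 1), 200, replace = TRUE)
        g <- ifelse(stats::runif(200) < 0.85, f, -f)
        ep <- simulate_epochs(cbind(f = f), code, snr = 0.7, seed = 50 + s,
                              times = c(0.14, 0.15, 0.16))
        fit_b2b_at_time(ep$X[, , 2], cbind(f = f, g = g),
                        n_splits = 30, seed = 100 + s)$beta
      })
    }, numeric(2))
    t(betas)    # subjects x c(f, g)
  })
}

# Latency-decoding r over a four-point drift grid at fixed moderate SNR,
# planted on the shared onset-evoked component with a flat envelope.
fx_latency_grid <- function() {
  fx("latency_grid", function() {
    lay <- sensor_layout(24)
    vapply(c(0, 0.5, 1.25, 2.5), function(dr) {
      code <- make_code(lay, "onset", drift_rate = dr, seed = 1,
                        window = c(0, 0.6), envelope = "boxcar")
      ep <- simulate_epochs(matrix(1, 200, 1, dimnames = list(NULL, "onset")),
                            code, snr = 0.4, seed = 6)
      decode_latency(ep, seed = 7)$r
    }, numeric(1))
  })
}

# Zero-noise anagram reconstruction (shared by unit and acceptance checks).
fx_seqsim_clean <- function() {
  fx("seqsim_clean", function() {
    tmpl <- make_code(sensor_layout(24), c("voicing", "plosive"),
                      drift_rate = 6.25, seed = 2, fs = 100)
    resp <- synthesize_sequence_responses(enumerate_anagrams(), tmpl,
                                          noise_sd = 0, seed = 3)
    list(resp = resp,
         rec = reconstruct_history(resp, n_perm = 2000, seed = 4))
  })
}
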