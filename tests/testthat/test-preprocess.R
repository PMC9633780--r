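# TRF confound removal, epoching, mel front end.

smooth_noise <- function(n, seed) {
  withr::with_seed(seed, {
    x <- as.numeric(stats::filter(stats::rnorm(n), rep(0.2, 5), sides = 2))
    x[is.na(x)] <- 0
    x
  })
}

test_that("the TRF recovers a planted linear dependence on the envelope", {
  n <- 4000
  env <- smooth_noise(n, 1)
  pit <- smooth_noise(n, 2)
  data <- rbind(2 * env + 0.1 * stats::rnorm(n), stats::rnorm(n))
  trf <- fit_trf(data, env, pit, fs = 250)
  expect_equal(length(trf$alphas), 10)               # ten-value lambda grid
  expect_equal(range(trf$alphas), c(1e-6, 1e+6))
  expect_gt(max(trf$mean_score), 0.45)               # mean over a clean + a noise channel
  res <- residualize(data, trf)
  # planted channel: residual variance < 5% of input variance
  expect_lt(stats::var(res[1, ]) / stats::var(data[1, ]), 0.05)
  # in-sample residuals are (near-)orthogonal to the prediction
  res_in <- residualize(data, trf, held_out = FALSE)
  pred_in <- data - res_in
  expect_lt(abs(stats::cor(res_in[1, ], pred_in[1, ])), 0.05)
  expect_error(fit_trf(data, rep(0, n), pit, fs = 250), "constant regressor")
})

test_that("a zero-weight TRF leaves the recording unchanged", {
  n <- 1000
  env <- smooth_noise(n, 3); pit <- smooth_noise(n, 4)
  data <- matrix(stats::rnorm(2 * n), 2)
  trf <- fit_trf(data, env, pit, fs = 250)
  trf$coef <- lapply(trf$coef, function(m) m * 0)
  trf$ch_mu <- trf$ch_mu * 0                          # predictions become zero
  expect_equal(residualize(data, trf), data)
  expect_error(residualize(data[, 1:10], trf), "shape")
})

test_that("epoching yields the canonical 201-sample grid and drops edge events", {
  ev <- sample_stream(toy_lexicon(), 10, seed = 2)
  ann <- annotate_stream(ev, toy_lexicon())
  code <- make_code(sensor_layout(12), c("voicing", "plosive"), 6.25, seed = 3)
  rec <- simulate_recording(ev, ann, code, sim_config(snr = 2), seed = 4)
  ep <- suppressMessages(epoch_events(rec))
  expect_equal(length(ep$times), 201)
  expect_equal(range(ep$times), c(-0.2, 0.6))
  expect_equal(mean(diff(ep$times)), 0.004, tolerance = 1e-12)
  # conservation: events in = trials out + dropped
  expect_equal(nrow(ev), dim(ep)[1] + length(attr(ep, "dropped")))
  # the first event (onset ~0) lacks its 200 ms pre-window and is dropped
  expect_true(1 %in% attr(ep, "dropped"))
  expect_error(suppressMessages(
    epoch_events(rec, onsets = c(0.0), fs = rec$fs)), "no valid events")
})

test_that("epoching commutes with summation for non-overlapping recordings", {
  ev <- tibble::tibble(label = "p", onset = 1.0, duration = 0.08,
                       word = "pa", word_id = 1L, sentence_id = 1L)
  lay <- sensor_layout(8)
  d1 <- matrix(stats::rnorm(8 * 3000), 8)
  d2 <- matrix(stats::rnorm(8 * 3000), 8)
  e1 <- epoch_events(d1, onsets = 1.0, fs = 1000, layout = lay)
  e2 <- epoch_events(d2, onsets = 1.0, fs = 1000, layout = lay)
  e12 <- epoch_events(d1 + d2, onsets = 1.0, fs = 1000, layout = lay)
  expect_equal(e12$X, e1$X + e2$X, tolerance = 1e-8)
})

test_that("decoding of a confound-driven pseudo-feature drops to chance after residualisation", {
  lex <- toy_lexicon()
  ev <- sample_stream(lex, 60, sim_config(word_gap_max = 0.25), seed = 5)
  ann <- annotate_stream(ev, lex)
  # no phonetic code at all: channels driven only by the acoustic envelope
  zero_ann <- ann
  zero_ann$voicing <- 0
  code <- make_code(sensor_layout(12), "voicing", 0, seed = 6)
  rec <- simulate_recording(ev, zero_ann, code,
                            sim_config(snr = 3, word_gap_max = 0.25,
                                       confound_gain_envelope = 1),
                            seed = 7)
  y <- ann$word_onset            # word-onset phonemes follow an envelope dip
  ep_raw <- suppressMessages(epoch_events(rec))
  y_kept <- y[ep_raw$annotation_index]
  t_use <- which(ep_raw$times >= -0.05 & ep_raw$times <= 0.15)
  small <- epoch_set(ep_raw$X[, , t_use], ep_raw$times[t_use], ep_raw$layout)
  auc_raw <- mean(auc_decode(small, y_kept, seed = 8)$auc)
  trf <- fit_trf(rec)
  resid <- residualize(rec, trf)
  ep_res <- suppressMessages(epoch_events(resid))
  small_res <- epoch_set(ep_res$X[, , t_use], ep_res$times[t_use], ep_res$layout)
  auc_res <- mean(auc_decode(small_res, y_kept, seed = 8)$auc)
  expect_gt(auc_raw, 0.60)
  expect_lt(abs(auc_res - 0.5), 0.06)
})

test_that("the mel front end has 208 triangular bands over 1-11250 Hz", {
  fs <- 22050
  tone <- sin(2 * pi * 1000 * seq(0, 0.8, by = 1 / fs))
  mb <- mel_branch(tone, fs)
  expect_equal(nrow(mb$power), 208)
  # a pure 1 kHz tone concentrates power at the matching band, stably
  peak_band <- apply(mb$power, 2, which.max)
  expect_equal(stats::median(mb$band_centers_hz[peak_band]), 1000,
               tolerance = 0.05 * 1000)
  expect_lt(stats::sd(peak_band) / mean(peak_band), 0.2)
  # silence maps to (numerically) zero power
  expect_lt(max(mel_branch(rep(0, 5000), fs)$power), 1e-12)
  expect_error(mel_branch(numeric(0), fs), "empty audio")
})
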