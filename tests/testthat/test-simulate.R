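# Synthetic generator: streams, planted codes, recordings.

test_that("sampled streams follow the configured duration distribution", {
  ev <- sample_stream(toy_lexicon(), 3300, seed = 1)
  expect_gt(nrow(ev), 10000)
  expect_equal(mean(ev$duration) * 1000, 78, tolerance = 2)   # within 2 ms
  expect_true(all(ev$duration > 0.02))
  # contiguous onsets within each word
  one_word <- ev[ev$word_id == 1, ]
  expect_equal(one_word$onset[-1],
               (one_word$onset + one_word$duration)[-nrow(one_word)],
               tolerance = 1e-9)
  # determinism under a fixed seed
  expect_identical(ev, sample_stream(toy_lexicon(), 3300, seed = 1))
  expect_error(sample_stream(toy_lexicon(), 0), "positive")
})

test_that("planted codes have the declared geometry", {
  lay <- sensor_layout(208)
  expect_equal(nrow(lay), 208)
  expect_true(all(is.finite(lay$x)) && all(lay$x^2 + lay$y^2 <= 1 + 1e-9))
  # static limit: all-latency patterns equal
  st <- make_code(lay, c("a", "b"), drift_rate = 0, seed = 1)
  expect_equal(st$W[1, , 1], st$W[1, , dim(st$W)[3]])
  # unit-norm spatial pattern at each latency
  dn <- make_code(lay, c("a", "b"), drift_rate = 6.25, seed = 1)
  norms <- apply(dn$W, c(1, 3), function(w) sqrt(sum(w^2)))
  expect_equal(as.vector(norms), rep(1, length(norms)), tolerance = 1e-9)
  # decorrelation: pattern at 80 ms nearly orthogonal to onset pattern
  l80 <- which.min(abs(dn$latencies - 0.08))
  expect_lt(abs(cor(dn$W[1, , 1], dn$W[1, , l80])), 0.5)
  # distinct features have near-orthogonal patterns at 208 channels
  expect_lt(abs(cor(dn$W[1, , 1], dn$W[2, , 1])), 0.2)
  expect_error(make_code(sensor_layout(2), c("a", "b", "c")), "fewer channels")
})

test_that("recordings superpose linearly and respect the SNR contract", {
  lex <- lexicon(c("pa", "ta"), c("p a", "t a"), c(1, 1))
  ev2 <- tibble::tibble(label = c("p", "a"), onset = c(0, 0.08),
                        duration = c(0.08, 0.08), word = "pa",
                        word_id = 1L, sentence_id = 1L)
  ann2 <- annotate_stream(ev2, lex)
  code <- make_code(sensor_layout(12), c("voicing", "plosive"),
                    drift_rate = 6.25, seed = 4)
  cfg0 <- sim_config(snr = Inf)
  both <- simulate_recording(ev2, ann2, code, cfg0, seed = 1)
  r1 <- simulate_recording(ev2[1, ], ann2[1, ], code, cfg0, seed = 1)
  r2 <- simulate_recording(ev2[2, ], ann2[2, ], code, cfg0, seed = 1)
  n <- min(ncol(r1$data), ncol(r2$data), ncol(both$data))
  expect_equal(both$data[, 1:n],
               r1$data[, 1:n] + r2$data[, 1:n], tolerance = 1e-10)
  # single event equals its feature-weighted pattern at onset
  l1 <- 10   # a latency index of the stored code
  s <- floor(ev2$onset[1] * both$fs) + 1 + (l1 - 1) * round(both$fs / code$fs)
  expected <- ann2$voicing[1] * code$envelope[l1] * code$W["voicing", , l1] +
    ann2$plosive[1] * code$envelope[l1] * code$W["plosive", , l1]
  expect_equal(r1$data[, s], expected, tolerance = 1e-10)
  # SNR = 0 gives a recording uncorrelated with the planted patterns
  noise <- simulate_recording(ev2, ann2, code, sim_config(snr = 0), seed = 2)
  expect_lt(abs(cor(as.vector(noise$data[, 1:200]),
                    as.vector(both$data[, 1:200]))), 0.1)
  # seed reproducibility is bit-exact
  again <- simulate_recording(ev2, ann2, code, sim_config(snr = 1), seed = 3)
  again2 <- simulate_recording(ev2, ann2, code, sim_config(snr = 1), seed = 3)
  expect_identical(again$data, again2$data)
  expect_error(simulate_recording(ev2, ann2, code, cfg0, duration = 0.1),
               "extend past")
})

test_that("the audio branch is static and active only during the phoneme", {
  ev <- sample_stream(toy_lexicon(), 4, seed = 11)
  ann <- annotate_stream(ev, toy_lexicon())
  aud <- simulate_audio_branch(ev[1, ], ann[1, ], sim_config(snr = Inf),
                               seed = 3, n_bands = 32)
  # energy confined to the phoneme's acoustic extent
  fs <- aud$fs
  on <- floor(ev$onset[1] * fs) + 1
  off <- on + round(ev$duration[1] * fs) + round(fs / 250)
  act <- sqrt(colMeans(aud$data^2))
  expect_gt(mean(act[on:(off - 5)]), 10 * mean(act[(off + 10):length(act)]))
  # pattern constant while active (static code, unit envelope)
  expect_gt(cor(aud$data[, on + 1], aud$data[, on + 5]), 0.999)
})

test_that("directly simulated epochs carry the planted code", {
  lay <- sensor_layout(16)
  code <- make_code(lay, "voicing", drift_rate = 0, seed = 2)
  Y <- rand_pm1(40, "voicing", seed = 3)
  ep <- simulate_epochs(Y, code, snr = Inf, seed = 4)
  expect_equal(dim(ep), c(40, 16, 201))
  t0 <- which.min(abs(ep$times - 0.15))
  l <- which.min(abs(code$latencies - 0.15))
  expect_equal(ep$X[1, , t0],
               Y[1, 1] * code$envelope[l] * code$W[1, , l], tolerance = 1e-9)
  # no signal before onset
  expect_equal(max(abs(ep$X[, , ep$times < 0])), 0)
})
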