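# Coefficient topographies, trajectories, latency decoding.

test_that("unregularised coefficients equal hand-computed OLS and recover planted patterns", {
  # 2-channel toy system against lm()
  withr::local_seed(1)
  X <- matrix(rnorm(80), 40, 2)
  y <- X %*% c(1.5, -2) + rnorm(40, sd = 0.1)
  ep <- epoch_set(array(X, dim = c(40, 2, 1)), 0, sensor_layout(2))
  W <- unregularized_coefficients(ep, cbind(f = y))
  ols <- stats::lm(y ~ X)$coefficients[-1]
  expect_equal(as.numeric(W[1, , 1]), unname(ols), tolerance = 1e-8)
  # planted static code, no noise: recovered topography matches the pattern
  lay <- sensor_layout(12)
  code <- make_code(lay, "f", 0, seed = 2)
  Y <- rand_pm1(100, "f", seed = 3)
  epc <- simulate_epochs(Y, code, snr = 30, seed = 4, times = c(0.148, 0.152))
  Wc <- unregularized_coefficients(epc, Y)
  expect_gt(abs(cor(Wc[1, , 1], code$W[1, , 38])), 0.95)
  # guard rails
  expect_error(unregularized_coefficients(epoch_set(array(0, c(10, 12, 1)),
                                                    0, lay), Y[1:10, , drop = FALSE]),
               "too few trials")
})

test_that("trajectory projections read topography location off the sensor axes", {
  lay <- sensor_layout(64)
  n_t <- 12
  anterior <- as.numeric(lay$y > 0.2)
  posterior <- as.numeric(lay$y < -0.2)
  # topography entirely anterior vs entirely posterior
  W <- array(0, dim = c(2, 64, n_t), dimnames = list(c("a", "p"), NULL, NULL))
  for (tt in seq_len(n_t)) {
    W[1, , tt] <- anterior
    W[2, , tt] <- posterior
  }
  traj <- project_trajectory(W, lay)
  expect_gt(min(traj$y[traj$feature == "a"]), max(traj$y[traj$feature == "p"]))
  # left-right symmetric topography sits between the extremes of lateralised ones
  sym <- abs(lay$y)
  left <- as.numeric(lay$x < -0.2)
  right <- as.numeric(lay$x > 0.2)
  W2 <- array(c(sym, left, right), dim = c(64, 3, 1))
  W2 <- aperm(W2, c(2, 1, 3))
  dimnames(W2) <- list(c("sym", "left", "right"), NULL, NULL)
  tr2 <- project_trajectory(W2, lay)
  expect_gt(tr2$x[tr2$feature == "sym"], tr2$x[tr2$feature == "left"])
  expect_lt(tr2$x[tr2$feature == "sym"], tr2$x[tr2$feature == "right"])
  # anterior-marching code: y-projection increases monotonically
  Wm <- array(0, dim = c(1, 64, n_t), dimnames = list("march", NULL, NULL))
  centers <- seq(-0.8, 0.8, length.out = n_t)
  for (tt in seq_len(n_t)) {
    Wm[1, , tt] <- exp(-((lay$y - centers[tt])^2) / 0.1)
  }
  trm <- project_trajectory(Wm, lay)
  expect_gt(stats::cor(trm$y, seq_len(n_t)), 0.9)
  expect_gt(trm$y[n_t] - trm$y[1], 0.3)
})

test_that("the trajectory structure metric rewards smooth far-ranging drifts", {
  # constant trajectory scores exactly 0
  traj_const <- tibble::tibble(feature = "f", time = 1:20,
                               x = rep(0.5, 20), y = rep(0.2, 20))
  class(traj_const) <- c("phonseq_trajectory", class(traj_const))
  expect_equal(trajectory_structure(traj_const)$structure, 0)
  # smooth monotone drift beats white jitter of equal range
  withr::local_seed(5)
  smooth_xy <- seq(0, 1, length.out = 40)
  jitter_xy <- sample(smooth_xy)
  mk <- function(z) {
    tr <- tibble::tibble(feature = "f", time = seq_along(z), x = z, y = z)
    class(tr) <- c("phonseq_trajectory", class(tr)); tr
  }
  expect_gt(trajectory_structure(mk(smooth_xy))$structure,
            trajectory_structure(mk(jitter_xy))$structure)
  expect_error(trajectory_structure(mk(c(0, 1))), "at least 10")
  # reflection of an axis leaves the metric unchanged
  tr <- mk(smooth_xy); tr$x <- -tr$x
  expect_equal(trajectory_structure(tr)$structure,
               trajectory_structure(mk(smooth_xy))$structure)
})

test_that("planted drifting codes reject the shuffled-label trajectory null", {
  lay <- sensor_layout(16)
  times <- seq(0, 0.28, by = 0.01)
  Y <- rand_pm1(200, "voicing", seed = 8)
  code <- make_code(lay, "voicing", 6.25, seed = 2, fs = 100,
                    envelope = "boxcar")
  ep <- simulate_epochs(Y, code, snr = 4, seed = 3, times = times)
  tn <- trajectory_null_test(ep, Y, lay, n_perm = 100, seed = 4)
  expect_lt(tn$p, 0.01)
  expect_equal(tn$floor, 0.01)
  expect_gt(tn$observed, max(tn$null))
})

test_that("latency decoding reflects drift: chance on noise, strong on drifting codes", {
  lay <- sensor_layout(24)
  # pure noise: mean prediction collapses to 250 ms, r ~ 0
  noise_ep <- simulate_epochs(matrix(0, 650, 1, dimnames = list(NULL, "onset")),
                              make_code(lay, "onset", 0, seed = 1),
                              snr = 0, seed = 2)
  lat0 <- decode_latency(noise_ep, seed = 3)
  expect_gte(nrow(lat0$predictions), 10000)
  expect_equal(mean(lat0$predictions$predicted_ms), 250, tolerance = 5)
  expect_lt(abs(lat0$r), 0.1)
  # static code: stationary pattern carries no latency information
  static_ep <- simulate_epochs(matrix(1, 200, 1, dimnames = list(NULL, "onset")),
                               make_code(lay, "onset", 0, seed = 1,
                                         window = c(0, 0.6),
                                         envelope = "boxcar"),
                               snr = 0.4, seed = 6)
  expect_lt(abs(decode_latency(static_ep, seed = 7)$r), 0.1)
  # strongly drifting code at high SNR: r > 0.9
  drift_ep <- simulate_epochs(matrix(1, 200, 1, dimnames = list(NULL, "onset")),
                              make_code(lay, "onset", 2.5, seed = 1,
                                        window = c(0, 0.6),
                                        envelope = "boxcar"),
                              snr = 3, seed = 6)
  lat_d <- decode_latency(drift_ep, seed = 7)
  expect_gt(lat_d$r, 0.9)
  # predictions stay within the training label range (ridge shrinkage)
  expect_true(all(lat_d$predictions$predicted_ms > 100 - 30 &
                    lat_d$predictions$predicted_ms < 400 + 30))
  expect_error(decode_latency(drift_ep, crop = c(-0.5, 0.4)), "crop window")
})

test_that("latency-decoding r increases with drift rate at fixed SNR", {
  rs <- fx_latency_grid()      # drift 0, 0.5, 1.25, 2.5 at SNR 0.4
  expect_true(all(diff(rs) > 0))
  expect_lt(abs(rs[1]), 0.1)
})
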