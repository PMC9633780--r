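# Temporal generalisation: static vs dynamic dissociation, alignment,
# overlap, ridge angle, position generalisation, subset comparison.

test_that("the TG diagonal equals the per-timepoint B2B fit under shared splits", {
  lay <- sensor_layout(12)
  code <- make_code(lay, "f", 6.25, seed = 1, fs = 50)
  Y <- rand_pm1(80, "f", seed = 2)
  times <- c(0.1, 0.14, 0.18)
  ep <- simulate_epochs(Y, code, snr = 1, seed = 3, times = times)
  tg <- tg_fit_eval(ep, Y, n_splits = 4, seed = 9)
  splits <- phonseq:::b2b_splits(80, 4, seed = 9)
  for (tt in seq_along(times)) {
    lone <- fit_b2b_at_time(ep$X[, , tt], Y, splits = splits)
    expect_equal(unname(mean(lone$beta)), tg$score[tt, tt], tolerance = 1e-10)
  }
})

test_that("static codes give square TG surfaces and dynamic codes narrow diagonals", {
  maps <- fx_tg_maps()
  dvr_s <- diag_vs_rows(maps$static, 4)
  dvr_d <- diag_vs_rows(maps$dynamic, 4)
  # static: row duration ~ diagonal duration
  expect_gt(dvr_s$ratio, 0.8)
  # dynamic (80 ms drift): rows much shorter than the ~300 ms diagonal
  expect_lt(dvr_d$ratio, 0.4)
  expect_gte(dvr_d$row_ms, 60)
  expect_lte(dvr_d$row_ms, 100)
  expect_gt(dvr_d$diag_ms, 200)
  # paired t across the train-time axis, df = n_times - 1
  expect_equal(dvr_d$df, length(maps$dynamic$times) - 1L)
  expect_gt(dvr_d$t, 2)
  # empty suprathreshold set is flagged, not an error
  flat <- maps$static; flat$score <- flat$score * 0
  expect_warning(res0 <- diag_vs_rows(flat, 4), "no suprathreshold")
  expect_equal(res0$diag_ms, 0)
})

test_that("pure-noise TG surfaces have no excess suprathreshold cells", {
  lay <- sensor_layout(12)
  tgs <- lapply(1:6, function(s) {
    code <- make_code(lay, "f", 0, seed = 1, fs = 25)
    Y <- rand_pm1(80, "f", seed = 30 + s)
    ep <- simulate_epochs(matrix(0, 80, 1, dimnames = list(NULL, "f")), code,
                          snr = 0, seed = 40 + s,
                          times = seq(-0.2, 0.6, by = 0.04))
    tg_fit_eval(ep, Y, n_splits = 3, seed = 50 + s)
  })
  tm <- tg_tmap(tgs)
  # t > 4 with 6 subjects has nominal tail probability ~ 0.005; allow 4x
  expect_lt(mean(tm$score > 4), 0.02)
})

test_that("word-clock alignment shifts positions by the phoneme rate", {
  maps <- fx_tg_maps()
  pos <- fx_positions(maps$dynamic)
  expect_equal(pos$P1$shift_ms, 0)          # P1 unshifted
  expect_equal(pos$P3$shift_ms, 160)        # P3 at +160 ms
  expect_equal(pos$P5$shift_ms, 320)
  backward <- align_to_word_clock(list("P-1" = maps$dynamic,
                                       "P-3" = maps$dynamic), step_ms = 80)$tg
  expect_equal(backward$`P-3`$shift_ms, -160)
  expect_error(align_to_word_clock(list(P1 = maps$dynamic), step_ms = 0),
               "positive")
  # composite stacks shifted diagonals
  comp <- align_to_word_clock(pos, step_ms = 80)$composite
  expect_setequal(unique(comp$position), paste0("P", 1:5))
  expect_equal(min(comp$time_ms[comp$position == "P2"]) -
                 min(comp$time_ms[comp$position == "P1"]), 80)
})

test_that("overlap fraction dissociates static from dynamic codes", {
  maps <- fx_tg_maps()
  ov_s <- overlap_fraction(fx_positions(maps$static), 4)
  ov_d <- overlap_fraction(fx_positions(maps$dynamic), 4)
  expect_gt(ov_s, 80)
  expect_lt(ov_d, 20)
  # bounded in [0, 100]
  expect_true(ov_s <= 100 && ov_d >= 0)
  # excluding edge positions keeps the dissociation
  expect_gt(overlap_fraction(fx_positions(maps$static), 4,
                             exclude_edges = TRUE), 80)
  # identical unshifted surfaces overlap fully; far-shifted diagonals not at all
  same <- align_to_word_clock(list(P1 = maps$static, P2 = maps$static),
                              step_ms = 1e-9)
  expect_error(align_to_word_clock(list(P1 = maps$static), step_ms = -1),
               "positive")
  ident <- list(P1 = maps$static, P2 = maps$static)
  ident <- lapply(ident, function(x) { x$shift_ms <- 0; x })
  expect_equal(overlap_fraction(ident, 4), 100)
  disjoint <- align_to_word_clock(list(P1 = maps$dynamic, P2 = maps$dynamic),
                                  step_ms = 5000)$tg
  expect_equal(overlap_fraction(disjoint, 4), 0)
})

test_that("ridge angle is 45 degrees for matched dynamics and follows constructed slopes", {
  maps <- fx_tg_maps()
  ang <- ridge_angle(maps$dynamic, 4)
  expect_gt(ang, 42); expect_lt(ang, 48)
  # constructed ridge with test dynamics twice as fast: slope 1/2 -> 26.6 deg
  n <- 41
  times <- seq(0, 0.4, length.out = n)
  sc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- round(2 * (i - n / 2) + n / 2)    # d(test)/d(train) = 2
    for (dj in -1:1) {
      jj <- j + dj
      if (jj >= 1 && jj <= n) sc[i, jj] <- 10
    }
  }
  tg2 <- phonseq:::new_tg(sc, times, "f")
  expect_equal(as.numeric(ridge_angle(tg2, 4)), atan(1 / 2) * 180 / pi,
               tolerance = 1)
  # translation of the ridge along the time axes leaves the angle unchanged
  tg2b <- tg2; tg2b$shift_ms <- 120
  expect_equal(as.numeric(ridge_angle(tg2b, 4)), as.numeric(ridge_angle(tg2, 4)))
  # horizontal ridge (static limit): a single train row is degenerate
  sch <- matrix(0, n, n); sch[20, 5:35] <- 10
  expect_warning(res <- ridge_angle(phonseq:::new_tg(sch, times, "f"), 4),
                 "degenerate")
  expect_true(is.na(res))
  # near-horizontal ridge tends to 0 degrees
  sch2 <- sch; sch2[19:21, 5:35] <- 10
  expect_lt(as.numeric(ridge_angle(phonseq:::new_tg(sch2, times, "f"), 4)), 10)
  expect_error(ridge_angle(phonseq:::new_tg(matrix(0, n, n), times, "f"), 4),
               "fewer than 10")
})

test_that("a position-invariant code generalises across positions; a specific one does not", {
  lay <- sensor_layout(16)
  times <- seq(-0.1, 0.4, by = 0.02)
  n_half <- 90
  code1 <- make_code(lay, "voicing", 0, seed = 1, fs = 50)
  code2 <- make_code(lay, "voicing", 0, seed = 99, fs = 50)   # distinct pattern
  Y1 <- rand_pm1(n_half, "voicing", seed = 21)
  Y2 <- rand_pm1(n_half, "voicing", seed = 22)
  e1 <- simulate_epochs(Y1, code1, snr = 2, seed = 11, times = times)
  e2_inv <- simulate_epochs(Y2, code1, snr = 2, seed = 12, times = times)
  e2_spec <- simulate_epochs(Y2, code2, snr = 2, seed = 12, times = times)
  pos <- c(rep("P1", n_half), rep("P2", n_half))
  Y <- rbind(Y1, Y2)
  score_in_window <- function(g) {
    vapply(split(g$score[g$time > 0.05 & g$time < 0.25],
                 g$group[g$time > 0.05 & g$time < 0.25]), mean, numeric(1))
  }
  inv <- score_in_window(
    generalize_across_positions(cat_epochs(e1, e2_inv), Y, pos,
                                test_groups = c("P1", "P2"),
                                n_splits = 6, seed = 5))
  spec <- score_in_window(
    generalize_across_positions(cat_epochs(e1, e2_spec), Y, pos,
                                test_groups = c("P1", "P2"),
                                n_splits = 6, seed = 5))
  expect_gt(inv["P2"], 0.8 * inv["P1"])     # cross ~ within
  expect_lt(abs(spec["P2"]), 0.15)          # cross at chance
  expect_gt(spec["P1"], 0.5)
  expect_error(generalize_across_positions(e1, Y1, rep("P1", n_half),
                                           test_groups = "P9"),
               "empty group 'P9'")
})

test_that("duration-scaled drift makes long phonemes generalise longer", {
  lay <- sensor_layout(16)
  times <- seq(-0.2, 0.6, by = 0.02)
  n <- 160
  durs <- rep(c(0.045, 0.135), each = n / 2)     # short vs long quartile means
  code <- make_code(lay, "onset", 6.25, seed = 5, fs = 50,
                    duration_scaled = TRUE)
  Yn <- rand_pm1(n, "onset", seed = 31)
  ep <- simulate_epochs(Yn, code, snr = 1, seed = 6, times = times,
                        durations = durs)
  grp <- ifelse(durs < 0.09, "short", "long")
  tgs <- tg_fit_eval(ep, Yn, n_splits = 3, seed = 7, groups = grp)
  thr <- 0.25 * max(diag(tgs$long$score))
  row_long <- diag_vs_rows(tgs$long, thr)$row_ms
  row_short <- diag_vs_rows(tgs$short, thr)$row_ms
  expect_gt(row_long, row_short + 20)
})

test_that("subset comparison on identical groups shows no systematic difference", {
  lay <- sensor_layout(12)
  code <- make_code(lay, "f", 0, seed = 8, fs = 25)
  Y <- rand_pm1(120, "f", seed = 9)
  ep <- simulate_epochs(Y, code, snr = 1, seed = 10,
                        times = seq(-0.2, 0.6, by = 0.04))
  grp <- rep(c("a", "b"), 60)                  # arbitrary identical halves
  sc <- subset_compare(ep, Y, grp, n_splits = 5, seed = 11)
  wide <- tidyr::pivot_wider(sc, names_from = "group", values_from = "score")
  expect_gt(stats::t.test(wide$a, wide$b, paired = TRUE)$p.value, 0.05)
  expect_error(subset_compare(ep, Y, rep(NA_character_, 120)), "no non-missing")
  # window restriction clips the output
  win <- subset_compare(ep, Y, grp, n_splits = 2, seed = 12,
                        window = c(0, 0.2))
  expect_true(all(win$time >= 0 & win$time <= 0.2))
})
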