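# Temporal generalisation (TG): train a decoder at one latency, evaluate it
# at all others. A square suprathreshold region indicates a stable (static)
# code; a narrow diagonal indicates a dynamic code whose topography drifts
# with latency. Scores here are B2B encoder betas averaged over features, so
# covariate control carries over to the TG surface.

new_tg <- function(score, times, features, subset = NA_character_,
                   shift_ms = 0, n_splits = NA_integer_) {
  structure(list(score = score, times = times, features = features,
                 subset = subset, shift_ms = shift_ms, n_splits = n_splits),
            class = "phonseq_tg")
}

#' @export
print.phonseq_tg <- function(x, ...) {
  cat(sprintf("<phonseq_tg> %d x %d train x test surface%s\n",
              nrow(x$score), ncol(x$score),
              if (!is.na(x$subset)) paste0(" [", x$subset, "]") else ""))
  invisible(x)
}

#' Temporal generalisation surface of B2B decoding
#'
#' For each training timepoint a B2B decoder is fitted on a random half of
#' trials; its decoded features at every test timepoint (standardised with
#' the training-half statistics of that timepoint) are regressed on the true
#' features of the held half, and the encoder diagonal (averaged over
#' `features`) is the score of cell (train, test). The diagonal of the
#' surface equals the [b2b_timecourse()] score under the same splits.
#'
#' @inheritParams b2b_timecourse
#' @param features features over which the encoder diagonal is averaged
#'   (default: all columns of `Y`).
#' @param groups optional per-trial grouping (e.g. phoneme position): the
#'   decoder is trained on the training half of all trials and evaluated
#'   separately on each group's held trials, returning one surface per group.
#' @return a `phonseq_tg` (train x test score matrix), or a named list of
#'   them when `groups` is given.
#' @export
tg_fit_eval <- function(epochs, Y, features = NULL, n_splits = 10,
                        seed = NULL, alphas_G = ridge_alpha_grid(),
                        alphas_H = ridge_alpha_grid(), groups = NULL) {
  Y <- check_b2b_inputs(at_time(epochs, 1), Y)
  features <- features %||% colnames(Y)
  f_idx <- match(features, colnames(Y))
  if (anyNA(f_idx)) abort("`features` must name columns of Y")
  n <- nrow(Y)
  n_t <- length(epochs$times)
  grp <- if (is.null(groups)) rep("all", n) else as.character(groups)
  levels_g <- unique(grp[!is.na(grp)])
  acc <- lapply(levels_g, function(g) matrix(0, n_t, n_t))
  names(acc) <- levels_g
  splits <- b2b_splits(n, n_splits, seed)
  for (s in seq_along(splits)) {
    tr <- splits[[s]]
    te_all <- setdiff(seq_len(n), tr)
    # training-half standardisation statistics at every timepoint
    mu_t <- matrix(0, n_t, dim(epochs$X)[2])
    sd_t <- matrix(1, n_t, dim(epochs$X)[2])
    for (tt in seq_len(n_t)) {
      Xt <- at_time(epochs, tt)[tr, , drop = FALSE]
      mu_t[tt, ] <- colMeans(Xt)
      sd_t[tt, ] <- col_sds(Xt)
    }
    te_groups <- lapply(levels_g, function(g) te_all[grp[te_all] == g])
    names(te_groups) <- levels_g
    designs <- lapply(te_groups, function(te) {
      if (length(te) < 2) NULL else ridge_design(Y[te, , drop = FALSE])
    })
    # pre-standardised test data per group and timepoint (training-half
    # statistics of the matching timepoint)
    Xte_z <- lapply(levels_g, function(g) {
      te <- te_groups[[g]]
      if (length(te) < 2) return(NULL)
      lapply(seq_len(n_t), function(tt) {
        scale_by(at_time(epochs, tt)[te, , drop = FALSE], mu_t[tt, ], sd_t[tt, ])
      })
    })
    names(Xte_z) <- levels_g
    for (t_train in seq_len(n_t)) {
      Xtr <- scale_by(at_time(epochs, t_train)[tr, , drop = FALSE],
                      mu_t[t_train, ], sd_t[t_train, ])
      G <- ridge_cv(Xtr, Y[tr, , drop = FALSE], alphas = alphas_G)
      for (g in levels_g) {
        if (is.null(designs[[g]])) next
        for (t_test in seq_len(n_t)) {
          Yhat <- ridge_predict(G, Xte_z[[g]][[t_test]])
          H <- ridge_cv(designs[[g]], Yhat, alphas = alphas_H)
          acc[[g]][t_train, t_test] <- acc[[g]][t_train, t_test] +
            mean(diag(H$coef)[f_idx])
        }
      }
    }
  }
  out <- lapply(levels_g, function(g) {
    new_tg(acc[[g]] / length(splits), epochs$times, features, subset = g,
           n_splits = length(splits))
  })
  names(out) <- levels_g
  if (is.null(groups)) out[["all"]] else out
}

#' Group-level t surface across subjects
#'
#' One-sample t statistic (against zero) per TG cell over a list of
#' per-subject surfaces with identical axes.
#'
#' @param tgs list of `phonseq_tg` objects, one per subject.
#' @return a `phonseq_tg` whose `score` is the t map; `n_subjects` attribute
#'   records the group size.
#' @export
tg_tmap <- function(tgs) {
  arr <- simplify2array(lapply(tgs, function(x) x$score))
  n <- length(tgs)
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- apply(arr, c(1, 2), stats::sd)
  tmat <- mu / (sd_ / sqrt(n))
  out <- new_tg(tmat, tgs[[1]]$times, tgs[[1]]$features,
                subset = tgs[[1]]$subset, shift_ms = tgs[[1]]$shift_ms,
                n_splits = tgs[[1]]$n_splits)
  attr(out, "n_subjects") <- n
  out
}

tg_mask <- function(tg, threshold) tg$score > threshold

#' Diagonal versus row generalisation durations
#'
#' Quantifies code dynamics: the duration of above-threshold decoding along
#' the diagonal (how long the information is present) versus the mean
#' duration along rows (how long any one training pattern stays informative).
#' A static code gives a ratio near 1; a dynamic code gives rows much
#' shorter than the diagonal. The t statistic is a paired t across the
#' train-time axis between the per-train-time diagonal and row run lengths
#' (df = number of timepoints - 1, i.e. 200 on the standard 201-sample grid).
#'
#' @param tg a `phonseq_tg` (score or group-level t surface).
#' @param threshold suprathreshold cutoff on the surface's own scale.
#' @return list: `diag_ms` (longest contiguous diagonal run), `row_ms` (mean
#'   of per-row longest runs over rows with any suprathreshold cell),
#'   `ratio`, `t`, `df`, `p`.
#' @export
diag_vs_rows <- function(tg, threshold) {
  mask <- tg_mask(tg, threshold)
  dt_ms <- 1000 * mean(diff(tg$times))
  if (!any(mask)) {
    warn("no suprathreshold cells; durations are zero and t undefined")
    return(list(diag_ms = 0, row_ms = 0, ratio = NA_real_,
                t = NA_real_, df = NA_integer_, p = NA_real_))
  }
  n_t <- nrow(mask)
  dmask <- diag(mask)
  diag_runs <- integer(n_t)
  if (any(dmask)) {
    runs <- true_runs(dmask)
    for (r in seq_len(nrow(runs))) {
      diag_runs[runs[r, 1]:runs[r, 2]] <- runs[r, 2] - runs[r, 1] + 1L
    }
  }
  row_runs <- vapply(seq_len(n_t), function(i) longest_run(mask[i, ]), integer(1))
  diag_ms <- longest_run(dmask) * dt_ms
  rows_with <- row_runs > 0
  row_ms <- mean(row_runs[rows_with]) * dt_ms
  tt <- tryCatch(stats::t.test(diag_runs, row_runs, paired = TRUE),
                 error = function(e) NULL)
  list(diag_ms = diag_ms, row_ms = row_ms, ratio = row_ms / diag_ms,
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = n_t - 1L,
       p = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Generalisation of a position-trained decoder across positions
#'
#' Trains B2B decoders on a random half of the trials of one phoneme
#' position (e.g. word-onset, P1) and evaluates the encoder betas on held
#' trials of each requested position group, per timepoint.
#'
#' @inheritParams b2b_timecourse
#' @param positions character vector, one position label per trial (e.g.
#'   `"P1"`, `"P2"`, `"P-1"`).
#' @param train_group position used for training (default `"P1"`).
#' @param test_groups positions to evaluate (default
#'   `c("P1", "P2", "P3", "P-1", "P-2")`).
#' @param features features over which betas are averaged.
#' @return tibble with columns `time`, `group`, `score` (split-averaged).
#' @export
generalize_across_positions <- function(epochs, Y, positions,
                                        train_group = "P1",
                                        test_groups = c("P1", "P2", "P3", "P-1", "P-2"),
                                        features = NULL, n_splits = 10,
                                        seed = NULL,
                                        alphas_G = ridge_alpha_grid(),
                                        alphas_H = ridge_alpha_grid()) {
  positions <- as.character(positions)
  pool <- which(positions == train_group)
  if (length(pool) < 4) abort(sprintf("empty or too-small group '%s'", train_group))
  for (g in test_groups) {
    if (!any(positions == g)) abort(sprintf("empty group '%s'", g))
  }
  b2b_eval_grouped(epochs, Y, train_pool = pool,
                   groups = stats::setNames(lapply(test_groups, function(g) {
                     which(positions == g)
                   }), test_groups),
                   features = features, n_splits = n_splits, seed = seed,
                   alphas_G = alphas_G, alphas_H = alphas_H)
}

#' Compare decoding between trial subsets
#'
#' Decoders are trained on the full training split (all trials); the held
#' split is grouped into the supplied bins (duration quartiles, surprisal or
#' entropy bins, word-length halves, ...) and scored separately per bin.
#' Per-bin timecourses from several subjects can then be passed to
#' [two_condition_cluster_test()].
#'
#' @inheritParams b2b_timecourse
#' @param grouping factor/character vector, one bin label per trial (`NA`
#'   trials are never used for evaluation).
#' @param features features over which betas are averaged.
#' @param window optional time window (s) to restrict the output to.
#' @return tibble with columns `time`, `group`, `score`.
#' @export
subset_compare <- function(epochs, Y, grouping, features = NULL,
                           n_splits = 10, seed = NULL, window = NULL,
                           alphas_G = ridge_alpha_grid(),
                           alphas_H = ridge_alpha_grid()) {
  grouping <- as.character(grouping)
  lev <- unique(grouping[!is.na(grouping)])
  if (length(lev) < 1) abort("no non-missing bins in `grouping`")
  groups <- stats::setNames(lapply(lev, function(g) which(grouping == g)), lev)
  if (any(lengths(groups) == 0)) abort("empty bin in `grouping`")
  out <- b2b_eval_grouped(epochs, Y, train_pool = seq_len(nrow(as.matrix(Y))),
                          groups = groups, features = features,
                          n_splits = n_splits, seed = seed,
                          alphas_G = alphas_G, alphas_H = alphas_H)
  if (!is.null(window)) {
    out <- dplyr::filter(out, .data$time >= window[1], .data$time <= window[2])
  }
  out
}

# Shared engine: train on a random half of `train_pool`, evaluate encoder
# betas per timepoint on each group's trials outside the training half.
b2b_eval_grouped <- function(epochs, Y, train_pool, groups, features = NULL,
                             n_splits = 10, seed = NULL,
                             alphas_G = ridge_alpha_grid(),
                             alphas_H = ridge_alpha_grid()) {
  Y <- check_b2b_inputs(at_time(epochs, 1), Y)
  features <- features %||% colnames(Y)
  f_idx <- match(features, colnames(Y))
  n_t <- length(epochs$times)
  acc <- matrix(0, n_t, length(groups))
  cnt <- matrix(0, n_t, length(groups))
  splits <- with_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      sample(train_pool, floor(length(train_pool) / 2))
    })
  })
  for (s in seq_along(splits)) {
    tr <- splits[[s]]
    te_groups <- lapply(groups, function(g) setdiff(g, tr))
    designs <- lapply(te_groups, function(te) {
      if (length(te) < 2) NULL else ridge_design(Y[te, , drop = FALSE])
    })
    for (tt in seq_len(n_t)) {
      Xt <- at_time(epochs, tt)
      mu <- colMeans(Xt[tr, , drop = FALSE])
      sd_ <- col_sds(Xt[tr, , drop = FALSE])
      G <- ridge_cv(scale_by(Xt[tr, , drop = FALSE], mu, sd_),
                    Y[tr, , drop = FALSE], alphas = alphas_G)
      for (gi in seq_along(te_groups)) {
        te <- te_groups[[gi]]
        if (length(te) < 2) next
        Yhat <- ridge_predict(G, scale_by(Xt[te, , drop = FALSE], mu, sd_))
        H <- ridge_cv(designs[[gi]], Yhat, alphas = alphas_H)
        acc[tt, gi] <- acc[tt, gi] + mean(diag(H$coef)[f_idx])
        cnt[tt, gi] <- cnt[tt, gi] + 1
      }
    }
  }
  score <- acc / pmax(cnt, 1)
  tibble::tibble(
    time = rep(epochs$times, times = length(groups)),
    group = rep(names(groups), each = n_t),
    score = as.vector(score)
  )
}

parse_position <- function(label) {
  m <- regmatches(label, regexec("^P(-?)([0-9]+)$", label))[[1]]
  if (length(m) == 0) abort(sprintf("unparseable position label '%s'", label))
  k <- as.integer(m[3])
  if (m[2] == "-") -k else k
}

#' Align per-position TG surfaces to the word clock
#'
#' Shifts the test axis of each position's surface by the average latency
#' from one phoneme to the next: position `Pk` moves forward by
#' `(k-1) * step_ms` relative to word onset, and `P-k` backwards by
#' `(k-1) * step_ms` relative to word offset. The composite stacks the
#' per-position diagonal scores on the shifted axis.
#'
#' @param tg_per_position named list of `phonseq_tg` (names like `"P1"`,
#'   `"P-2"`). Missing positions are simply absent.
#' @param step_ms average phoneme-to-phoneme latency in ms (default 80).
#' @return list with `tg` (the shifted surfaces, `shift_ms` filled) and
#'   `composite` (tibble `time_ms`, `position`, `score` of shifted
#'   diagonals, ready for a stacked plot).
#' @export
align_to_word_clock <- function(tg_per_position, step_ms = 80) {
  if (step_ms <= 0) abort("`step_ms` must be positive")
  shifted <- purrr::imap(tg_per_position, function(tg, nm) {
    k <- parse_position(nm)
    tg$shift_ms <- (abs(k) - 1) * step_ms * sign(k)
    tg$subset <- nm
    tg
  })
  composite <- purrr::imap_dfr(shifted, function(tg, nm) {
    tibble::tibble(time_ms = 1000 * tg$times + tg$shift_ms,
                   position = nm, score = diag(tg$score))
  })
  list(tg = shifted, composite = composite)
}

#' Overlap of suprathreshold TG cells between neighbouring positions
#'
#' After word-clock alignment, the fraction of suprathreshold (train, test)
#' cells of each position that are also suprathreshold for at least one of
#' its temporally adjacent positions (the previous or next phoneme in the
#' same family, forward `P1, P2, ...` or backward `..., P-2, P-1`),
#' averaged over positions, as a percentage. High overlap indicates
#' neighbouring phonemes sharing neural patterns (static code); low overlap
#' indicates individuated representations (dynamic code).
#'
#' @param tg_per_position named list of `phonseq_tg` with `shift_ms` set
#'   (see [align_to_word_clock()]); names parseable as positions.
#' @param threshold suprathreshold cutoff (on the surface's own scale, e.g.
#'   a group t of 4).
#' @param exclude_edges drop the first (`P1`) and last (`P-1`) positions.
#' @return percentage in `[0, 100]`.
#' @export
overlap_fraction <- function(tg_per_position, threshold = 4,
                             exclude_edges = FALSE) {
  if (length(tg_per_position) < 2) abort("need at least two positions")
  if (exclude_edges) {
    tg_per_position <- tg_per_position[
      !names(tg_per_position) %in% c("P1", "P-1")]
    if (length(tg_per_position) < 2) abort("need at least two positions after exclusion")
  }
  ks <- vapply(names(tg_per_position), parse_position, integer(1))
  cells <- lapply(tg_per_position, function(tg) {
    mask <- tg_mask(tg, threshold)
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(character(0))
    test_ms <- round(1000 * tg$times[idx[, 2]] + tg$shift_ms)
    train_ms <- round(1000 * tg$times[idx[, 1]])
    paste(train_ms, test_ms)
  })
  fams <- split(seq_along(ks), sign(ks))
  fracs <- c()
  for (fam in fams) {
    ord <- fam[order(abs(ks[fam]))]
    if (length(ord) < 2) next
    for (i in seq_along(ord)) {
      a <- cells[[ord[i]]]
      if (!length(a)) next
      nb <- unlist(cells[ord[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 &
                                             c(i - 1, i + 1) <= length(ord)]]])
      fracs <- c(fracs, mean(a %in% nb))
    }
  }
  if (length(fracs) == 0) {
    warn("no suprathreshold cells in any position")
    return(0)
  }
  100 * mean(fracs)
}

#' Principal-axis angle of the suprathreshold TG ridge
#'
#' Fits the first principal axis to the (test-time, train-time) coordinates
#' of the suprathreshold cells and returns its angle in degrees within
#' (0, 90): 45 degrees means test-time dynamics proceed at training speed;
#' smaller angles mean faster test dynamics, larger angles slower.
#'
#' @param tg a `phonseq_tg`.
#' @param threshold suprathreshold cutoff.
#' @param score_weighted weight cells by their score instead of equally.
#' @return angle in degrees, with attribute `n_cells`; `NA` with a warning
#'   for degenerate (single row/column) regions.
#' @export
ridge_angle <- function(tg, threshold, score_weighted = FALSE) {
  mask <- tg_mask(tg, threshold)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 10) abort("fewer than 10 suprathreshold cells")
  train_ms <- 1000 * tg$times[idx[, 1]]
  test_ms <- 1000 * tg$times[idx[, 2]] + tg$shift_ms
  if (stats::sd(train_ms) == 0 || stats::sd(test_ms) == 0) {
    warn("degenerate suprathreshold region (single row or column)")
    return(structure(NA_real_, n_cells = nrow(idx)))
  }
  w <- if (score_weighted) tg$score[idx] - threshold else rep(1, nrow(idx))
  w <- pmax(w, 0); w <- w / sum(w)
  mu <- c(sum(w * test_ms), sum(w * train_ms))
  d <- cbind(test_ms - mu[1], train_ms - mu[2])
  covm <- crossprod(d * sqrt(w))
  v <- eigen(covm, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(abs(v[2]), abs(v[1])) * 180 / pi
  structure(ang, n_cells = nrow(idx))
}
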