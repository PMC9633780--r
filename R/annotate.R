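# Phoneme-stream annotation: the 31-column design matrix.
#
# Each phoneme event is annotated with 14 binary phonetic features, 3
# information-theoretic measures (surprisal, cohort entropy, log sequence
# frequency), 8 unit-boundary features and 6 positional features. Binary
# features are coded +/-1; continuous features are z-scored within the
# annotated stream. Cohort statistics restart at every word boundary.

#' Names of the 31 annotation feature columns
#'
#' @param which one of `"all"`, `"phonetic"`, `"information"`, `"boundary"`,
#'   `"positional"`.
#' @return character vector of feature column names.
#' @export
annotation_feature_names <- function(which = c("all", "phonetic", "information",
                                               "boundary", "positional")) {
  which <- match.arg(which)
  phonetic <- phonetic_feature_names()
  information <- c("surprisal", "entropy", "seq_freq")
  boundary <- c("word_onset", "word_offset", "syllable_onset", "syllable_offset",
                "root_onset", "prefix_onset", "suffix_onset", "sentence_onset")
  positional <- c("pos_in_word", "pos_to_offset", "pos_in_syllable",
                  "syll_in_word", "word_in_sentence", "pos_in_sentence")
  switch(which,
         all = c(phonetic, information, boundary, positional),
         phonetic = phonetic, information = information,
         boundary = boundary, positional = positional)
}

# Naive vowel-centred syllabification: vowels are nuclei; the consonant
# immediately preceding a nucleus joins its syllable (single-consonant
# onsets), remaining consonants attach to the preceding nucleus.
syllable_index <- function(labels, feature_table) {
  is_v <- feature_table$vowel[match(labels, feature_table$phoneme)] == 1
  n <- length(labels)
  nuclei <- which(is_v)
  if (length(nuclei) == 0) return(rep(1L, n))
  syl <- integer(n)
  for (k in seq_len(n)) {
    if (is_v[k]) {
      syl[k] <- which(nuclei == k)
    } else if (k < n && is_v[k + 1]) {
      syl[k] <- which(nuclei == k + 1)       # onset of the next nucleus
    } else {
      prev <- nuclei[nuclei < k]
      syl[k] <- if (length(prev)) which(nuclei == max(prev)) else 1L
    }
  }
  syl
}

pm1 <- function(x) 2 * as.numeric(x) - 1   # 0/1 or logical -> -1/+1

#' Annotate a phoneme event stream
#'
#' Builds the full 31-column feature table (design matrix `Y`) for a stream
#' of phoneme events grouped into words. Surprisal and cohort entropy are
#' computed from the word-internal prefix at each phoneme; log sequence
#' frequency is the log of the summed frequency of the cohort consistent with
#' the sequence heard so far (current phoneme included).
#'
#' @param events tibble with one row per phoneme event: columns `label`,
#'   `onset` (s), `duration` (s), `word` (lexicon word id), `word_id`
#'   (integer token index), and optionally `sentence_id`.
#' @param lex a [lexicon()] covering every word in `events`.
#' @param feature_table a [build_feature_table()] covering every label.
#' @param log_base base for the log sequence frequency (default 10).
#' @return tibble of class `phonseq_annotation`: event metadata columns
#'   (`label`, `onset`, `duration`, `word_id`, `word`, `sentence_id`,
#'   `pos_from_onset`, `pos_from_offset`, `word_length`) followed by the 31
#'   feature columns, binary ones coded +/-1 and continuous ones z-scored.
#' @export
annotate_stream <- function(events, lex, feature_table = NULL, log_base = 10) {
  stopifnot(is.data.frame(events), nrow(events) > 0)
  req <- c("label", "onset", "duration", "word", "word_id")
  miss <- setdiff(req, names(events))
  if (length(miss)) abort(paste("events is missing column(s):", paste(miss, collapse = ", ")))
  if (any(events$duration <= 0)) abort("event durations must be positive")
  if (is.null(feature_table)) {
    feature_table <- build_feature_table(unique(events$label))
  }
  unk <- setdiff(unique(events$word), lex$word)
  if (length(unk)) abort(sprintf("word(s) not in lexicon: %s", paste(unk, collapse = ", ")))

  events <- dplyr::arrange(events, .data$onset)
  if (!"sentence_id" %in% names(events)) events$sentence_id <- 1L

  ft <- feature_table
  fmat <- as.matrix(ft[match(events$label, ft$phoneme), phonetic_feature_names()])
  if (anyNA(fmat)) abort("feature table does not cover every event label")

  n <- nrow(events)
  meta <- events[, c("label", "onset", "duration", "word_id", "word", "sentence_id")]
  pos_on <- pos_off <- wlen <- integer(n)
  surp <- entr <- sqfreq <- numeric(n)
  syl_idx <- pos_syl <- syl_onset <- syl_offset <- integer(n)
  root_on <- pref_on <- suff_on <- numeric(n)

  for (wid in unique(events$word_id)) {
    idx <- which(events$word_id == wid)
    w <- events$word[idx[1]]
    li <- lookup_word(lex, w)
    seq_w <- split_phonemes(lex$phonemes[li])[[1]]
    labs <- events$label[idx]
    if (!identical(labs, seq_w)) {
      abort(sprintf("events of word token %s do not match lexicon entry '%s'", wid, w))
    }
    m <- length(idx)
    pos_on[idx] <- seq_len(m)
    pos_off[idx] <- seq_len(m) - m - 1L     # P-1 = -1 for last phoneme
    wlen[idx] <- m
    for (k in seq_len(m)) {
      prefix <- labs[seq_len(k - 1L)]
      surp[idx[k]] <- surprisal(prefix, labs[k], lex)
      coh_k <- cohort_of(labs[seq_len(k)], lex)
      entr[idx[k]] <- -sum((coh_k$frequency / sum(coh_k$frequency)) *
                             log2(coh_k$frequency / sum(coh_k$frequency)))
      sqfreq[idx[k]] <- log(sum(coh_k$frequency), base = log_base)
    }
    syl <- syllable_index(labs, ft)
    syl_idx[idx] <- syl
    pos_syl[idx] <- stats::ave(seq_len(m), syl, FUN = seq_along)
    syl_onset[idx] <- as.integer(!duplicated(syl))
    syl_offset[idx] <- as.integer(!duplicated(syl, fromLast = TRUE))
    pa <- lex$prefix_at[li]; sa <- lex$suffix_at[li]
    root_start <- if (!is.na(pa)) pa + 1L else 1L
    root_on[idx] <- as.integer(seq_len(m) == root_start)
    pref_on[idx] <- as.integer(!is.na(pa) & seq_len(m) == 1L)
    suff_on[idx] <- as.integer(!is.na(sa) & seq_len(m) == sa)
  }

  word_onset <- as.integer(pos_on == 1L)
  word_offset <- as.integer(pos_off == -1L)
  first_word <- stats::ave(events$word_id, events$sentence_id, FUN = min)
  sentence_onset <- as.integer(events$word_id == first_word & pos_on == 1L)
  word_in_sent <- stats::ave(events$word_id, events$sentence_id,
                             FUN = function(w) match(w, sort(unique(w))))
  pos_in_sent <- stats::ave(seq_len(n), events$sentence_id, FUN = seq_along)

  feat <- tibble::tibble(!!!stats::setNames(
    lapply(seq_len(ncol(fmat)), function(j) pm1(fmat[, j])),
    colnames(fmat)))
  feat$surprisal <- zscore(surp)
  feat$entropy <- zscore(entr)
  feat$seq_freq <- zscore(sqfreq)
  feat$word_onset <- pm1(word_onset)
  feat$word_offset <- pm1(word_offset)
  feat$syllable_onset <- pm1(syl_onset)
  feat$syllable_offset <- pm1(syl_offset)
  feat$root_onset <- pm1(root_on)
  feat$prefix_onset <- pm1(pref_on)
  feat$suffix_onset <- pm1(suff_on)
  feat$sentence_onset <- pm1(sentence_onset)
  feat$pos_in_word <- zscore(pos_on)
  feat$pos_to_offset <- zscore(-pos_off)
  feat$pos_in_syllable <- zscore(pos_syl)
  feat$syll_in_word <- zscore(syl_idx)
  feat$word_in_sentence <- zscore(word_in_sent)
  feat$pos_in_sentence <- zscore(pos_in_sent)

  out <- dplyr::bind_cols(
    meta,
    tibble::tibble(pos_from_onset = pos_on, pos_from_offset = pos_off,
                   word_length = wlen,
                   surprisal_raw = surp, entropy_raw = entr),
    feat[, annotation_feature_names()]
  )
  class(out) <- c("phonseq_annotation", class(out))
  out
}

#' Extract the feature matrix from an annotation table
#'
#' @param annotation a [annotate_stream()] result.
#' @param which feature group as in [annotation_feature_names()].
#' @return numeric matrix (events x features).
#' @export
feature_matrix <- function(annotation, which = "all") {
  cols <- annotation_feature_names(which)
  as.matrix(annotation[, cols])
}

#' Append lagged phonetic feature columns
#'
#' Expands the 14 phonetic columns with their values for the `n_history`
#' preceding events of the stream (columns `<feature>_lag<h>`), giving
#' `14 * (n_history + 1)` phonetic columns. The first `h` events of the
#' stream, which have no lag-`h` predecessor, are padded with 0 (the
#' uninformative midpoint of the +/-1 coding).
#'
#' @param annotation a [annotate_stream()] result (or any tibble containing
#'   the 14 phonetic columns, ordered by onset).
#' @param n_history non-negative number of preceding phonemes.
#' @return the input with lag columns appended; attribute
#'   `"lagged_feature_cols"` lists the full lagged phonetic column set.
#' @export
lag_features <- function(annotation, n_history) {
  if (!is.numeric(n_history) || length(n_history) != 1 || n_history < 0) {
    abort("`n_history` must be a non-negative integer")
  }
  n_history <- as.integer(n_history)
  ph <- annotation_feature_names("phonetic")
  out <- annotation
  lag_cols <- ph
  if (n_history > 0) {
    for (h in seq_len(n_history)) {
      for (f in ph) {
        v <- annotation[[f]]
        lagged <- c(rep(0, min(h, length(v))),
                    v[seq_len(max(length(v) - h, 0))])
        nm <- sprintf("%s_lag%d", f, h)
        out[[nm]] <- lagged
        lag_cols <- c(lag_cols, nm)
      }
    }
  }
  attr(out, "lagged_feature_cols") <- lag_cols
  out
}

#' Read / write an annotation TSV
#'
#' UTF-8 tab-separated interchange format: metadata columns `label`,
#' `onset_s`, `duration_s`, `word_id`, `pos_from_onset`, `pos_from_offset`
#' plus the 31 named feature columns, `.` decimal separator.
#'
#' @param annotation a `phonseq_annotation` tibble.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  df <- as.data.frame(annotation)
  names(df)[names(df) == "onset"] <- "onset_s"
  names(df)[names(df) == "duration"] <- "duration_s"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", dec = ".")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  names(df)[names(df) == "onset_s"] <- "onset"
  names(df)[names(df) == "duration_s"] <- "duration"
  out <- tibble::as_tibble(df)
  class(out) <- c("phonseq_annotation", class(out))
  out
}
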