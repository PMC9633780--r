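#' Construct a lexicon
#'
#' A lexicon maps words to phoneme sequences and corpus frequency counts.
#' Cohort statistics (continuation probability, surprisal, cohort entropy)
#' are computed against this table, restarting at every word boundary.
#'
#' @param word character vector of unique word identifiers.
#' @param phonemes character vector of space-separated phoneme sequences
#'   (e.g. `"k a t"`), one per word.
#' @param frequency strictly positive numeric frequency counts `f(w)`.
#' @param prefix_at,suffix_at optional integer 1-based phoneme index at which
#'   a prefix ends / a suffix begins (`NA` for monomorphemic words); used for
#'   boundary feature columns.
#' @return a tibble of class `phonseq_lexicon` with columns `word`,
#'   `phonemes`, `frequency`, `prefix_at`, `suffix_at`.
#' @examples
#' lexicon(c("cat", "cab"), c("k a t", "k a b"), c(2, 1))
#' @export
lexicon <- function(word, phonemes, frequency, prefix_at = NA_integer_,
                    suffix_at = NA_integer_) {
  if (anyDuplicated(word)) abort("lexicon words must be unique")
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    abort("lexicon frequencies must be strictly positive")
  }
  if (any(!nzchar(trimws(phonemes)))) abort("phoneme sequences must be non-empty")
  out <- tibble::tibble(
    word = as.character(word),
    phonemes = as.character(phonemes),
    frequency = as.numeric(frequency),
    prefix_at = as.integer(prefix_at),
    suffix_at = as.integer(suffix_at)
  )
  class(out) <- c("phonseq_lexicon", class(out))
  out
}

split_phonemes <- function(x) strsplit(trimws(x), "\\s+")

#' Read / write a lexicon TSV
#'
#' Plain-text interchange format: UTF-8 TSV with columns `word`, `phonemes`
#' (space-separated), `frequency`, and optionally `prefix_at`, `suffix_at`.
#'
#' @param path file path.
#' @return `read_lexicon()` returns a `phonseq_lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  lexicon(df$word, df$phonemes, df$frequency,
          prefix_at = df$prefix_at %||% NA_integer_,
          suffix_at = df$suffix_at %||% NA_integer_)
}

#' @param lex a `phonseq_lexicon`.
#' @rdname read_lexicon
#' @export
write_lexicon <- function(lex, path) {
  utils::write.table(lex, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Toy lexicon used by the synthetic test bed
#'
#' A small constructed lexicon over the default phoneme inventory, with
#' frequency structure chosen so that cohorts shrink along words and
#' surprisal/entropy vary across positions. A few polymorphemic entries carry
#' prefix/suffix boundaries so all boundary features are exercised.
#'
#' @return a `phonseq_lexicon` tibble.
#' @export
toy_lexicon <- function() {
  lexicon(
    word = c("cat", "cab", "captain", "can", "dog", "dot", "pet", "pets",
             "pest", "pester", "pan", "pat", "sun", "sip", "sit", "song",
             "tap", "tan", "top", "mole", "mat", "man", "win", "wind",
             "red", "redo", "run", "ring", "hat", "hand", "kiss", "keep",
             "leg", "lip", "net", "nest", "vote", "fan", "zip", "gap"),
    phonemes = c("k a t", "k a b", "k a p t e n", "k a n", "d o g", "d o t",
                 "p e t", "p e t s", "p e s t", "p e s t @ r", "p a n",
                 "p a t", "s u n", "s i p", "s i t", "s o n g", "t a p",
                 "t a n", "t o p", "m o l", "m a t", "m a n", "w i n",
                 "w i n d", "r e d", "r i d u", "r u n", "r i n g", "h a t",
                 "h a n d", "k i s", "k i p", "l e g", "l i p", "n e t",
                 "n e s t", "v o t", "f a n", "z i p", "g a p"),
    frequency = c(20, 5, 2, 15, 18, 6, 12, 4, 3, 1, 7, 9, 10, 5, 11, 3,
                  8, 4, 6, 2, 7, 14, 9, 5, 13, 1, 10, 6, 8, 7, 4, 9,
                  5, 6, 7, 3, 4, 6, 2, 3),
    suffix_at = c(NA, NA, NA, NA, NA, NA, NA, 4L, NA, 5L, NA, NA, NA, NA,
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    prefix_at = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 2L, NA, NA,
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA)
  )
}

lookup_word <- function(lex, w) {
  i <- match(w, lex$word)
  if (is.na(i)) abort(sprintf("word '%s' is not in the lexicon", w))
  i
}

#' Cohort of a phoneme prefix
#'
#' The cohort is the set of lexicon words whose phoneme sequence begins with
#' `prefix`. An empty prefix returns the whole lexicon (the cohort before any
#' evidence has been heard). An empty cohort is returned as a zero-row tibble,
#' not an error.
#'
#' @param prefix character vector of phoneme symbols heard so far (may be
#'   length zero).
#' @param lex a [lexicon()].
#' @return tibble with columns `word`, `phonemes`, `frequency` for the cohort
#'   members.
#' @examples
#' cohort_of(c("k", "a"), toy_lexicon())
#' @export
cohort_of <- function(prefix, lex) {
  seqs <- split_phonemes(lex$phonemes)
  k <- length(prefix)
  if (k == 0L) return(tibble::as_tibble(lex[, c("word", "phonemes", "frequency")]))
  hit <- vapply(seqs, function(s) {
    length(s) >= k && all(s[seq_len(k)] == prefix)
  }, logical(1))
  tibble::as_tibble(lex[hit, c("word", "phonemes", "frequency")])
}

#' Continuation probability of the next phoneme given a cohort
#'
#' `P(p | C) = f(p) / sum_{p' in C} f(p')`, where `f(p)` is the summed word
#' frequency of cohort members whose next phoneme is `p`, so probabilities
#' over all attested continuations sum to one.
#'
#' @inheritParams cohort_of
#' @param next_phoneme single phoneme symbol.
#' @return probability in `[0, 1]`.
#' @examples
#' continuation_probability(c("k", "a"), "t", toy_lexicon())
#' @export
continuation_probability <- function(prefix, next_phoneme, lex) {
  coh <- cohort_of(prefix, lex)
  if (nrow(coh) == 0L) abort("undefined cohort: no words match the prefix")
  seqs <- split_phonemes(coh$phonemes)
  k <- length(prefix)
  nxt <- vapply(seqs, function(s) if (length(s) > k) s[k + 1L] else NA_character_,
                character(1))
  denom <- sum(coh$frequency[!is.na(nxt)])
  if (denom == 0) abort("undefined cohort: no continuations from this prefix")
  sum(coh$frequency[!is.na(nxt) & nxt == next_phoneme]) / denom
}

#' Phoneme surprisal in bits
#'
#' `-log2 P(p | C)` of the continuation probability; zero when the phoneme is
#' fully predictable.
#'
#' @inheritParams continuation_probability
#' @param phoneme the observed next phoneme.
#' @return surprisal in bits (non-negative).
#' @export
surprisal <- function(prefix, phoneme, lex) {
  p <- continuation_probability(prefix, phoneme, lex)
  if (p == 0) abort(sprintf("zero-probability continuation '%s'", phoneme))
  -log2(p)
}

#' Cohort entropy in bits
#'
#' Shannon entropy `-sum_w P(w|C) log2 P(w|C)` over the frequency-weighted
#' cohort members; zero for a singleton cohort, maximal (`log2 |C|`) for
#' uniform frequencies.
#'
#' @inheritParams cohort_of
#' @return entropy in bits.
#' @export
cohort_entropy <- function(prefix, lex) {
  coh <- cohort_of(prefix, lex)
  if (nrow(coh) == 0L) abort("undefined cohort: no words match the prefix")
  p <- coh$frequency / sum(coh$frequency)
  -sum(p * log2(p))
}
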