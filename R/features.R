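# Binary phonetic feature coding.
#
# Fourteen binary dimensions describe each phoneme: voicing, five manner
# classes (fricative, nasal, plosive, approximant, vowel) and eight place
# classes (central/low/mid/high vowel for vowels; coronal, glottal, labial,
# velar for consonants). Vowel place bits are zero for consonants and
# consonant place bits are zero for vowels.

#' Names of the fourteen binary phonetic features
#' @return character vector of length 14.
#' @export
phonetic_feature_names <- function() {
  c("voicing",
    "fricative", "nasal", "plosive", "approximant", "vowel",
    "central_vowel", "low_vowel", "mid_vowel", "high_vowel",
    "coronal", "glottal", "labial", "velar")
}

#' Default phonetic feature scheme
#'
#' Feature assignments for the package's default phoneme inventory (sixteen
#' consonants, five full vowels and schwa `@`). Each row gives the fourteen
#' 0/1 feature values for one phoneme.
#'
#' @return tibble with a `phoneme` column and fourteen 0/1 feature columns.
#' @export
default_feature_scheme <- function() {
  spec <- list(
    #          voi manner                  place
    "p" = list(0, "plosive",     "labial"),
    "b" = list(1, "plosive",     "labial"),
    "t" = list(0, "plosive",     "coronal"),
    "d" = list(1, "plosive",     "coronal"),
    "k" = list(0, "plosive",     "velar"),
    "g" = list(1, "plosive",     "velar"),
    "f" = list(0, "fricative",   "labial"),
    "v" = list(1, "fricative",   "labial"),
    "s" = list(0, "fricative",   "coronal"),
    "z" = list(1, "fricative",   "coronal"),
    "h" = list(0, "fricative",   "glottal"),
    "m" = list(1, "nasal",       "labial"),
    "n" = list(1, "nasal",       "coronal"),
    "l" = list(1, "approximant", "coronal"),
    "r" = list(1, "approximant", "coronal"),
    "w" = list(1, "approximant", "labial"),
    "a" = list(1, "vowel",       "low_vowel"),
    "e" = list(1, "vowel",       "mid_vowel"),
    "i" = list(1, "vowel",       "high_vowel"),
    "o" = list(1, "vowel",       "mid_vowel"),
    "u" = list(1, "vowel",       "high_vowel"),
    "@" = list(1, "vowel",       "central_vowel")
  )
  fn <- phonetic_feature_names()
  rows <- purrr::imap(spec, function(v, ph) {
    f <- stats::setNames(rep(0, 14), fn)
    f["voicing"] <- v[[1]]
    f[v[[2]]] <- 1
    f[v[[3]]] <- 1
    tibble::as_tibble_row(c(list(phoneme = ph), as.list(f)))
  })
  dplyr::bind_rows(rows)
}

#' Build a phonetic feature table for an inventory
#'
#' Validates that every inventory symbol is covered by the scheme and that the
#' vowel/consonant place partition holds, and returns the 14-column binary
#' feature table for exactly the requested inventory.
#'
#' @param inventory character vector of phoneme symbols.
#' @param scheme a feature-assignment table as returned by
#'   [default_feature_scheme()] (a `phoneme` column plus the fourteen 0/1
#'   feature columns).
#' @return tibble of class `phonseq_features`: `phoneme` + 14 binary columns.
#' @examples
#' ft <- build_feature_table(c("b", "p", "a"))
#' @export
build_feature_table <- function(inventory, scheme = default_feature_scheme()) {
  inventory <- unique(as.character(inventory))
  missing <- setdiff(inventory, scheme$phoneme)
  if (length(missing) > 0) {
    abort(sprintf("uncovered inventory: no feature assignment for phoneme(s) %s",
                  paste(sprintf("'%s'", missing), collapse = ", ")))
  }
  fn <- phonetic_feature_names()
  if (!all(fn %in% names(scheme))) {
    abort("scheme must contain all fourteen phonetic feature columns")
  }
  tab <- scheme[match(inventory, scheme$phoneme), c("phoneme", fn)]
  vals <- as.matrix(tab[, fn])
  if (!all(vals %in% c(0, 1))) abort("feature values must be binary 0/1")
  vowel_place <- c("central_vowel", "low_vowel", "mid_vowel", "high_vowel")
  cons_place <- c("coronal", "glottal", "labial", "velar")
  is_vowel <- vals[, "vowel"] == 1
  if (any(vals[is_vowel, cons_place] != 0) || any(vals[!is_vowel, vowel_place] != 0)) {
    abort("vowel place bits must be zero for consonants and vice versa")
  }
  out <- tibble::as_tibble(tab)
  class(out) <- c("phonseq_features", class(out))
  out
}
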