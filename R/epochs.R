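#' Epoch container
#'
#' The object every decoder consumes: a trials x channels x time tensor plus
#' its time grid, sensor layout and (optionally) the annotation rows the
#' trials correspond to. No baseline correction is ever applied.
#'
#' @param X numeric array, trials x channels x time.
#' @param times numeric vector of sample times in seconds relative to
#'   phoneme onset.
#' @param layout a [sensor_layout()] with one row per channel.
#' @param annotation_index optional integer vector mapping trials to rows of
#'   an annotation table.
#' @param seed seed recorded for provenance.
#' @return object of class `phonseq_epochs`.
#' @export
epoch_set <- function(X, times, layout, annotation_index = NULL, seed = NULL) {
  if (length(dim(X)) != 3) abort("X must be a trials x channels x time array")
  if (dim(X)[3] != length(times)) abort("time axis does not match `times`")
  if (dim(X)[2] != nrow(layout)) abort("channel axis does not match layout")
  structure(list(X = X, times = times, layout = layout,
                 annotation_index = annotation_index, seed = seed),
            class = "phonseq_epochs")
}

#' @export
print.phonseq_epochs <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<phonseq_epochs> %d trials x %d channels x %d samples (%.0f..%.0f ms)\n",
              d[1], d[2], d[3], 1000 * min(x$times), 1000 * max(x$times)))
  invisible(x)
}

#' @export
dim.phonseq_epochs <- function(x) dim(x$X)

# Slice the channel matrix at one timepoint: trials x channels.
at_time <- function(epochs, t_idx) epochs$X[, , t_idx, drop = TRUE]

#' Subset an epoch set by trial
#'
#' @param epochs an [epoch_set()].
#' @param i integer or logical trial index.
#' @return an [epoch_set()] with the selected trials.
#' @export
subset_epochs <- function(epochs, i) {
  epoch_set(epochs$X[i, , , drop = FALSE], epochs$times, epochs$layout,
            annotation_index = epochs$annotation_index[i], seed = epochs$seed)
}
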