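# ggplot2 methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot B2B beta / variance-share timecourses
#'
#' @param object a [b2b_timecourse()] result.
#' @param shares plot normalised shares (requires [variance_shares()])
#'   instead of raw betas.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phonseq_b2b <- function(object, shares = !is.null(object$rhat), ...) {
  df <- tidy(object)
  yvar <- if (shares) "rhat" else "beta"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[yvar]],
                                   colour = .data$feature)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from phoneme onset (s)",
                  y = if (shares) "share of explainable variance" else "B2B beta") +
    ggplot2::theme_minimal()
}

#' Plot a temporal-generalisation surface
#'
#' @param object a `phonseq_tg`.
#' @param threshold optional contour level drawn over the surface.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phonseq_tg <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$test_time,
                                        y = .data$train_time,
                                        fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "test time (s)", y = "train time (s)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$score),
                                   breaks = threshold, colour = "white")
  }
  p
}

#' Plot a coefficient-topography trajectory
#'
#' @param object a [project_trajectory()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phonseq_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$time)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~feature) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "left-right projection",
                  y = "posterior-anterior projection") +
    ggplot2::theme_minimal()
}

#' Plot lag-similarity from the anagram simulation
#'
#' @param object a [reconstruct_history()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phonseq_seqsim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$similarity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$lag) +
    ggplot2::labs(x = "history lag (1 = current phoneme)",
                  y = "cosine similarity") +
    ggplot2::theme_minimal()
}

#' Plot latency-decoder predictions
#'
#' @param object a [decode_latency()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phonseq_latency <- function(object, ...) {
  df <- object$predictions |>
    dplyr::group_by(.data$true_ms) |>
    dplyr::summarise(mean_pred = mean(.data$predicted_ms),
                     se = stats::sd(.data$predicted_ms) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_ms, y = .data$mean_pred)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = mean(object$predictions$true_ms),
                        linetype = 3, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pred - .data$se,
                                          ymax = .data$mean_pred + .data$se)) +
    ggplot2::labs(x = "true latency since onset (ms)",
                  y = "predicted latency (ms)") +
    ggplot2::theme_minimal()
}
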