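#' Plot CDR3 length distributions
#'
#' Frequency polygons of CDR3 length, one line per species (or per
#' repertoire in a named list).
#'
#' @param x A `vhh_repertoire` or a named list of them.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(x) {
  reps <- if (inherits(x, "vhh_repertoire")) list(x) else x
  if (is.null(names(reps))) {
    names(reps) <- vapply(reps, function(r) r$species[1], character(1))
  }
  df <- dplyr::bind_rows(
    lapply(reps, function(r) tibble::tibble(cdr3_length = r$cdr3_length)),
    .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(.data$cdr3_length, colour = .data$group)) +
    ggplot2::geom_freqpoly(binwidth = 1, ggplot2::aes(y =
      ggplot2::after_stat(.data$density))) +
    ggplot2::labs(x = "CDR3 length (residues)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of positional usage correlations
#'
#' Position-by-residue tile map of Pearson r between residue presence and
#' CDR3 length, with significance stars overlaid.
#'
#' @param report Output of [positional_usage_vs_length()] (optionally
#'   several regions bound together).
#' @return A ggplot object.
#' @export
plot_usage_heatmap <- function(report) {
  df <- dplyr::mutate(report,
                      pos = paste0(.data$position, .data$insertion))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$residue,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      is.na(.data$stars) | .data$stars == "ns", "", .data$stars)),
      size = 2.5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_grid(. ~ region, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "IMGT position", y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Feature versus CDR3 length with binned means
#'
#' Scatter of per-length bin means with standard-error bars and the
#' regression line through the bin means (the usual presentation of
#' length trends; inference itself uses all data points).
#'
#' @param data A data frame.
#' @param length_col,feature_col Column names (strings).
#' @return A ggplot object.
#' @export
plot_feature_vs_length <- function(data, feature_col,
                                   length_col = "cdr3_length") {
  br <- binned_mean_regression(data[[length_col]], data[[feature_col]])
  ggplot2::ggplot(br$bins, ggplot2::aes(.data$x, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      linewidth = 0.3, size = 0.3) +
    ggplot2::geom_abline(slope = br$slope, intercept = br$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "CDR3 length (residues)", y = feature_col) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.binned_regression <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$x, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      linewidth = 0.3, size = 0.3) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::theme_minimal()
}

#' Density and threshold of a conformation classification
#'
#' The kernel density of FR2-CDR3 distances with the bent/extended
#' threshold (when bimodal) marked.
#'
#' @param object A `cdr3_conformation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdr3_conformation <- function(object, ...) {
  p <- ggplot2::ggplot(object$density, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "FR2-CDR3 distance (Å)", y = "density") +
    ggplot2::theme_minimal()
  if (!object$unimodal) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
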