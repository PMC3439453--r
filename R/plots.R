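# False-colour palette conventional for FLIM displays (short = red/warm,
# long = blue/cool is instrument-dependent; here short->red, long->blue).
.flim_palette <- rev(c("#313695", "#4575b4", "#74add1", "#abd9e9", "#fee090",
                       "#fdae61", "#f46d43", "#d73027"))

#' Plot a FLIM lifetime image
#'
#' False-colour map of the per-pixel single-exponential lifetime; masked
#' pixels are blank.
#'
#' @param object A `flim_image` from [make_flim_image()].
#' @param limits Optional lifetime colour limits, ps.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flim_image
#' @export
autoplot.flim_image <- function(object, limits = NULL, ...) {
  df <- tidyr::expand_grid(x = seq_len(nrow(object$tau)) - 1,
                           y = seq_len(ncol(object$tau)) - 1)
  df$tau <- as.vector(object$tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$tau)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = .flim_palette, limits = limits,
                                  na.value = "black",
                                  name = expression(tau ~ "(ps)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("FLIM image (%s channel)", object$channel),
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a patient-level ROC curve
#'
#' @param object A `flim_roc` from [roc_auc_over_patients()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flim_roc
#' @export
autoplot.flim_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Patient-level ROC (AUC = %.2f)", object$auc),
                  x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a group-comparison report
#'
#' Dot plot of the per-parameter discrimination (Mann–Whitney AUC), ranked.
#'
#' @param object A `flim_group_comparison` from [group_summaries()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flim_group_comparison
#' @export
autoplot.flim_group_comparison <- function(object, ...) {
  df <- as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey") +
    ggplot2::labs(x = "AUC (BCC vs normal)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Class-separated histogram of one feature
#'
#' @param records Feature table with `class_label`.
#' @param parameter Feature column.
#' @param binwidth Optional bin width (Freedman–Diaconis default).
#' @return A ggplot.
#' @export
plot_feature_histogram <- function(records, parameter, binwidth = NULL) {
  h <- feature_histogram(records, parameter, binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$density,
                                  colour = .data$class_label)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(bcc = "#d73027", normal = "#4575b4"),
                                 name = NULL) +
    ggplot2::labs(x = parameter, y = "density") +
    ggplot2::theme_minimal()
}
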