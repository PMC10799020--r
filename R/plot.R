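#' Plot FRAP curves, optionally faceted by condition
#'
#' @param curves A curve tibble (one or many cells).
#' @param facet Facet by condition (default `TRUE` when the column exists).
#' @return A ggplot object.
#' @export
plot_frap_curves <- function(curves, facet = "condition" %in% names(curves)) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$t_s, y = .data$F_au,
                                    group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time after bleach (s)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (facet) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  p
}

#' Overlay a fitted recovery model on the measured curve
#'
#' @param object A `frap_fit` from [fit_frap()].
#' @param ... Unused.
#' @return A ggplot object: normalized data, fitted curve, and the fitted
#'   asymptote implied by the mobile fraction.
#' @export
autoplot.frap_fit <- function(object, ...) {
  dat <- object$curve
  fitted_df <- tibble::tibble(t_s = object$t_post, F_fit = object$fitted)
  asymptote <- (1 - object$Rf_hat) * object$f0 + object$Rf_hat
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s, y = .data$F_au)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = asymptote, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "time after bleach (s)", y = "normalized fluorescence",
      title = sprintf("R_f = %.2f, D = %.3g um^2/s (recovery %.0f%%)",
                      object$Rf_hat, object$D_hat, object$recovery_pct)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(data = fitted_df,
                                ggplot2::aes(y = .data$F_fit),
                                colour = "firebrick", linewidth = 0.7)
  }
  p
}

#' Bar plot of group means with SEM, in the style of FRAP figure panels
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  lab <- if (object$variable == "Rf") "mobile fraction R_f" else "D (um^2/s)"
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$group_label, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n), y = 0),
                       vjust = 1.5, size = 3) +
    ggplot2::labs(x = NULL, y = paste(lab, "(mean ± SEM)")) +
    ggplot2::theme_minimal()
}
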