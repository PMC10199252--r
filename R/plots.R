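# ggplot2 views of the three result types. These are deliberately plain:
# boxplots of per-repetition balanced accuracy, the lollipop selection-rate
# panel, and the module effect profile.

#' Boxplots of per-repetition balanced accuracy
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$bacs,
                  ggplot2::aes(x = .data$spec_id, y = .data$bac)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "balanced accuracy",
                  title = object$contrast %||% NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Lollipop plot of selection rates
#'
#' @param object a `selection_trace`.
#' @param top show only the `top` highest-rate variables (default 20).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, top = 20L, ...) {
  df <- head(tidy(object), top)
  df$variable_id <- factor(df$variable_id, levels = rev(df$variable_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selection_rate,
                                   y = .data$variable_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$selection_rate,
                                       yend = .data$variable_id),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 2) +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                guide = "none") +
    ggplot2::labs(x = "selection rate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of a module effect profile
#'
#' Shows each variable's improvement-oriented d versus retest, grouped by
#' attributed module; solid points mark specific effects (both comparisons
#' significant).
#'
#' @param object an `effect_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot effect_profile
#' @export
autoplot.effect_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_vs_retest,
                                   y = .data$variable_id,
                                   shape = .data$specific_effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "specific effect") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$module), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Cohen's d vs retest (improvement-oriented)", y = NULL) +
    ggplot2::theme_minimal()
}
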