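# ggplot2 views of the main result types.

#' Plot a structural-coefficient scan
#'
#' Arc count and MDL score against the structural coefficient; the flagged
#' elbow is highlighted.
#'
#' @param object An `sc_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sc_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("n_arcs", "mdl"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sc, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$elbow)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "structural coefficient",
                  y = NULL, title = "SC scan: network density vs score")
}

#' Forest plot of total and direct effects on the target
#'
#' @param object A `psem_effects` tibble (ideally from
#'   [effect_significance()], so intervals are available).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.psem_effects <- function(object, ...) {
  df <- as_tibble(object)
  long <- bind_rows(
    tibble(source = df$source, kind = "total", estimate = df$total_effect,
           lo = df$total_lo %||% NA_real_, hi = df$total_hi %||% NA_real_),
    tibble(source = df$source, kind = "direct", estimate = df$direct_effect,
           lo = df$direct_lo %||% NA_real_, hi = df$direct_hi %||% NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate, y = .data$source)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "effect on target (target units per source unit)",
                  y = NULL)
}

#' Plot per-class cross-validated ROC AUCs
#'
#' @param object A `crossval_auc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.crossval_auc <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "macro_auc"),
                        linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "target class", y = "one-vs-rest AUC",
                  title = "Jackknife classification of the target")
}
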