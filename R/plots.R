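# ggplot2 autoplot methods for the result types.

#' Plot a PRD curve
#'
#' Recall (beta, distribution coverage) on the x axis against precision
#' (alpha, sample quality) on the y axis; the ideal generator reaches the
#' top-right corner (1, 1).
#'
#' @param object An `stsg_prd`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stsg_prd <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$beta, y = .data$alpha)) +
    ggplot2::geom_path(linewidth = 0.4, colour = "steelblue") +
    ggplot2::geom_point(size = 0.5, colour = "steelblue") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = expression(beta ~ "(recall)"),
                  y = expression(alpha ~ "(precision)"),
                  title = "Precision-recall distribution") +
    ggplot2::theme_minimal()
}

#' Plot an association heatmap
#'
#' Masked (undefined) cells — zero-variance features — are shown blank.
#'
#' @param object An `stsg_assoc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stsg_assoc <- function(object, ...) {
  df <- tidy.stsg_assoc(object)
  df$var1 <- factor(df$var1, levels = rownames(object$matrix))
  df$var2 <- factor(df$var2, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$association)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey92") +
    ggplot2::labs(x = NULL, y = NULL, fill = "assoc.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot MIA precision curves
#'
#' Attack precision against the fraction of the training data known to the
#' adversary; 0 everywhere means the synthetic data revealed no
#' memberships under this attack.
#'
#' @param object An `stsg_mia`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stsg_mia <- function(object, ...) {
  ggplot2::ggplot(object$result,
                  ggplot2::aes(x = .data$known_fraction,
                               y = .data$precision)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fraction of training data known to adversary",
                  y = "attack precision",
                  title = sprintf("Membership inference (threshold %.2f)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot generator training traces
#'
#' One panel per recorded loss component over training steps.
#'
#' @param object An `stsg_generator`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stsg_generator <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace,
                            -dplyr::all_of(c("epoch", "step")),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "training step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold metric values of an evaluation report
#'
#' @param object An `stsg_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stsg_report <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, size = 1, colour = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold value",
                  title = sprintf("%s (%s backend)",
                                  object$provenance$approach,
                                  object$provenance$backend)) +
    ggplot2::theme_minimal()
}
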