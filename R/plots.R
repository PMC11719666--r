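#' Score plot of a PCA result
#'
#' @param object a [run_pca()] result.
#' @param components which two components to draw.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.seed_pca <- function(object, components = c(1, 2), ...) {
  df <- tidy(object, "scores")
  cx <- paste0("PC", components[1])
  cy <- paste0("PC", components[2])
  ggplot2::ggplot(df, ggplot2::aes(
    .data[[cx]], .data[[cy]],
    colour = .data$label
  )) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cx, object$explained_pct[components[1]]),
      y = sprintf("%s (%.1f%%)", cy, object$explained_pct[components[2]]),
      colour = NULL, title = "PCA score plot"
    ) +
    ggplot2::theme_minimal()
}

#' Score plot of a PLS-DA model
#'
#' @param object a [plsda_fit()] model.
#' @param components which two components to draw.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.plsda <- function(object, components = c(1, 2), ...) {
  ncomp <- ncol(object$scores)
  components <- components[components <= ncomp]
  if (length(components) < 2) components <- c(1, min(2, ncomp))
  df <- tibble::tibble(
    t1 = object$scores[, components[1]],
    t2 = object$scores[, min(components[2], ncomp)],
    label = object$labels
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2, colour = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("t[%d]", components[1]), y = sprintf("t[%d]", components[2]),
      colour = NULL,
      title = sprintf("PLS-DA scores (R2Y = %.3f, Q2 = %.3f)", object$R2Y, object$Q2)
    ) +
    ggplot2::theme_minimal()
}

#' Permutation-test validation plot
#'
#' R2Y and Q2 of each permuted model against its correlation with the
#' original labels, with the unpermuted model at correlation 1.
#'
#' @param object a [permutation_test()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.permutation_test <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object),
    cols = c("R2Y", "Q2"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$label_correlation, .data$value,
    colour = .data$metric
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "correlation with original labels", y = NULL, colour = NULL,
      title = sprintf("Permutation test (p = %.4g)", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of an evaluation report
#'
#' @param object a [train_eval()] report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      title = sprintf(
        "%s: test accuracy %.1f%%",
        object$model_kind, object$test_accuracy
      ),
      x = "predicted", y = "true"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Fire-ice scatter plot
#'
#' The fused 2-D representation of a dataset, one point per sample.
#'
#' @param data a tibble from [reduce_dataset()] (columns `fire`, `ice`,
#'   `label`).
#' @return A ggplot.
#' @export
plot_fire_ice <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$fire, .data$ice, colour = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "fire value", y = "ice value", colour = NULL,
      title = "Fire-ice fused representation"
    ) +
    ggplot2::theme_minimal()
}
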