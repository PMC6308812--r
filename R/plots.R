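#' Plot a ROC curve
#'
#' @param object A `drowsy_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drowsy_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation result
#'
#' Shows the inner-CV grid accuracy surface (averaged over outer folds) as
#' a heatmap over `log2(C)` and `log2(gamma)`.
#'
#' @param object A `drowsy_cv` from [nested_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drowsy_cv <- function(object, ...) {
  surf <- object$grid_surface
  df <- tidyr::expand_grid(
    C = as.numeric(sub("C=", "", rownames(surf))),
    gamma = as.numeric(sub("gamma=", "", colnames(surf)))
  )
  df$accuracy <- as.vector(t(surf))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$gamma), y = log2(.data$C),
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Inner-CV\naccuracy") +
    ggplot2::labs(x = expression(log[2](gamma)), y = expression(log[2](C)),
                  title = "Grid-search accuracy surface") +
    ggplot2::theme_minimal()
}

#' Plot an EEG recording trace
#'
#' @param object An [eeg_recording].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_recording <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$samples) - 1) / object$fs,
    voltage = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (signal units)",
                  title = sprintf("%s (%s, %s)", object$recording_id,
                                  object$subject_id, object$session)) +
    ggplot2::theme_minimal()
}
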