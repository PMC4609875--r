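#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::annotate("point", x = object$operating_point["fp"],
                      y = object$operating_point["tp"], shape = 4, size = 3) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  autoplot(object$roc, ...)
}

#' Plot the best-so-far fitness trace of an optimizer run
#'
#' @param object A `gsa_result` or `rgsa_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsa_result
#' @export
autoplot.gsa_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best fitness (minimized)") +
    ggplot2::theme_minimal()
}

#' @method autoplot rgsa_selection
#' @export
autoplot.rgsa_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$history),
                       fitness = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best wrapper fitness",
                  title = sprintf("%s gravitational search", object$variant)) +
    ggplot2::theme_minimal()
}
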