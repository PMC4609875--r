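#' Tidy per-feature view of a selection result
#'
#' @param x An `rgsa_selection`.
#' @param ... Unused.
#' @return Tibble with one row per candidate feature: `feature`, `position`
#'   (decoded agent coordinate) and `selected`.
#' @method tidy rgsa_selection
#' @export
tidy.rgsa_selection <- function(x, ...) {
  nf <- length(x$mask)
  tibble::tibble(feature = x$feature_names %||% paste0("f", seq_len(nf)),
                 position = x$positions[seq_len(nf)],
                 selected = x$mask)
}

#' One-row summary of a selection result
#'
#' @param x An `rgsa_selection`.
#' @param ... Unused.
#' @return One-row tibble: variant, subset size, hyperparameters, wrapper
#'   fitness and internal cross-validated accuracy.
#' @method glance rgsa_selection
#' @export
glance.rgsa_selection <- function(x, ...) {
  tibble::tibble(variant = x$variant, n_features = length(x$mask),
                 n_selected = sum(x$mask), C = x$C, sigma = x$sigma,
                 fitness = x$fitness, accuracy_cv = x$accuracy_cv,
                 iterations = x$config$max_iter)
}

#' Per-subject predictions of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `observed`, `pred`, `score` per held-out subject.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  x$predictions
}

#' One-row metric summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with confusion counts, sensitivity, specificity,
#'   accuracy, RMSE, MAE and AUC.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, rmse = x$rmse, mae = x$mae,
                 auc = x$auc)
}

#' Best-so-far fitness trace of an optimizer run
#'
#' @param x A `gsa_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness`.
#' @method tidy gsa_result
#' @export
tidy.gsa_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), best_fitness = x$history)
}

#' @method glance gsa_result
#' @export
glance.gsa_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 n_evaluations = x$n_evaluations,
                 variant = x$config$variant,
                 n_agents = x$config$n_agents,
                 iterations = x$config$max_iter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
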