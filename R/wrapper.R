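#' Decode an agent position into a feature mask and SVM hyperparameters
#'
#' The first `n_features` dimensions of the position threshold at 0.5 into a
#' binary feature mask; the last two decode log-uniformly into the SVM cost
#' `C` and kernel width `sigma`. An all-zero mask is repaired by enabling the
#' feature with the highest position value.
#'
#' @param position Numeric vector of length `n_features + 2` in `[0, 1]`.
#' @param n_features Number of candidate features.
#' @param c_range,sigma_range Two-element ranges (positive) decoded on a log
#'   scale.
#' @return An object of class `feature_mask`: logical `mask`, `C`, `sigma`,
#'   `featuresel` (number of selected features).
#' @export
decode_agent <- function(position, n_features,
                         c_range = c(0.1, 100), sigma_range = c(0.1, 10)) {
  stopifnot(length(position) == n_features + 2)
  mask <- position[seq_len(n_features)] > 0.5
  if (!any(mask)) mask[which.max(position[seq_len(n_features)])] <- TRUE
  decode_log <- function(u, rng) 10^(log10(rng[1]) + u * diff(log10(rng)))
  structure(list(mask = mask,
                 C = decode_log(position[n_features + 1], c_range),
                 sigma = decode_log(position[n_features + 2], sigma_range),
                 featuresel = sum(mask)),
            class = "feature_mask")
}

# stratified fold assignment, deterministic given the RNG state
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# standardize columns by training statistics; zero-variance columns get
# scale 1 so constant features pass through instead of producing NaN
standardize_by <- function(X, center, scl) {
  sweep(sweep(X, 2, center, `-`), 2, scl, `/`)
}

train_scaling <- function(X) {
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = colMeans(X), scale = scl)
}

svm_cv_accuracy <- function(X, y, C, sigma, fold) {
  k <- max(fold)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      maj <- names(which.max(table(y[tr])))
      correct <- correct + sum(y[!tr] == as.integer(maj))
      next
    }
    sc <- train_scaling(X[tr, , drop = FALSE])
    m <- e1071::svm(standardize_by(X[tr, , drop = FALSE], sc$center, sc$scale),
                    factor(y[tr], levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = 1 / (2 * sigma^2), scale = FALSE)
    pred <- as.integer(as.character(predict(
      m, standardize_by(X[!tr, , drop = FALSE], sc$center, sc$scale))))
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

# accuracy/parsimony combination the wrapper maximizes
wrapper_fitness_value <- function(accuracy, featuresel, theta = 0.7) {
  theta * accuracy + (1 - theta) / featuresel
}

#' Wrapper fitness of a feature mask
#'
#' `theta * accuracy + (1 - theta) / featuresel`, where accuracy is the
#' stratified k-fold cross-validated accuracy of an RBF SVM trained on the
#' masked features with the decoded hyperparameters. Higher is better; the
#' minimization engine receives the negated value. A classifier failure
#' yields fitness 0.
#'
#' @param mask A `feature_mask` from [decode_agent()].
#' @param X Numeric feature matrix (samples x features).
#' @param y Labels in \{+1, -1\}.
#' @param theta Weight of the accuracy term, default 0.7.
#' @param fold Fold assignment vector (see details in [rgsa_select()]); when
#'   `NULL` a stratified 5-fold split is drawn.
#' @return Scalar fitness in `[0, 1]` (to maximize).
#' @export
wrapper_fitness <- function(mask, X, y, theta = 0.7, fold = NULL) {
  stopifnot(inherits(mask, "feature_mask"), mask$featuresel >= 1)
  if (is.null(fold)) fold <- stratified_folds(y, 5)
  acc <- tryCatch(
    svm_cv_accuracy(X[, mask$mask, drop = FALSE], y, mask$C, mask$sigma, fold),
    error = function(e) NA_real_)
  if (is.na(acc)) return(0)
  wrapper_fitness_value(acc, mask$featuresel, theta)
}

#' Select features and SVM hyperparameters with the gravitational search
#'
#' Runs the (refined or classical) gravitational search over a
#' `n_features + 2`-dimensional unit cube; each agent decodes to a feature
#' subset plus `(C, sigma)` and is scored by [wrapper_fitness()]. The fold
#' assignment for the internal cross-validation is drawn once from the seed so
#' the fitness landscape is fixed during the search.
#'
#' @param data A data frame of candidate features, or a `tabular_dataset`.
#' @param labels Labels in \{+1, -1\}; ignored when `data` is a
#'   `tabular_dataset`.
#' @param config An [rgsa_config()].
#' @param theta Accuracy weight of the wrapper fitness.
#' @param c_range,sigma_range Hyperparameter decode ranges.
#' @param cv_folds Internal cross-validation folds (default 5).
#' @param seed RNG seed.
#' @return An object of class `rgsa_selection`: `selected` (feature names),
#'   `mask`, `C`, `sigma`, `fitness` (best wrapper fitness), `accuracy_cv`,
#'   `history` (best wrapper fitness per iteration), `variant`, `config`,
#'   `positions` (best agent position).
#' @export
rgsa_select <- function(data, labels = NULL,
                        config = rgsa_config(n_agents = 20, max_iter = 50),
                        theta = 0.7, c_range = c(0.1, 100),
                        sigma_range = c(0.1, 10), cv_folds = 5, seed = 1) {
  if (inherits(data, "tabular_dataset")) {
    labels <- data$labels
    data <- data$features
  }
  X <- as.matrix(data)
  if (is.null(labels)) stop("`labels` required", call. = FALSE)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(-1, 1)))
  if (theta <= 0 || theta >= 1) stop("`theta` must be in (0, 1)", call. = FALSE)
  nf <- ncol(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- stratified_folds(labels, cv_folds)
  fn <- function(pos) {
    fm <- decode_agent(pos, nf, c_range, sigma_range)
    -wrapper_fitness(fm, X, labels, theta = theta, fold = fold)
  }
  res <- gsa_optimize(fn, n_dim = nf + 2, config = config,
                      seed = seed + 1L)
  fm <- decode_agent(res$best_position, nf, c_range, sigma_range)
  acc <- svm_cv_accuracy(X[, fm$mask, drop = FALSE], labels, fm$C, fm$sigma,
                         fold)
  structure(list(selected = colnames(X)[fm$mask], mask = fm$mask,
                 C = fm$C, sigma = fm$sigma,
                 fitness = -res$best_fitness, accuracy_cv = acc,
                 history = -res$history, variant = config$variant,
                 config = config, positions = res$best_position,
                 feature_names = colnames(X)),
            class = "rgsa_selection")
}

#' @export
print.rgsa_selection <- function(x, ...) {
  cat(sprintf(
    "<rgsa_selection> %s variant: %d/%d features, C = %.3g, sigma = %.3g\n",
    x$variant, sum(x$mask), length(x$mask), x$C, x$sigma))
  cat(sprintf("  wrapper fitness %.4f (cv accuracy %.4f)\n",
              x$fitness, x$accuracy_cv))
  invisible(x)
}
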