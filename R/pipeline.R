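#' Default pipeline configuration
#'
#' @return Named list of stage parameter blocks with their defaults
#'   (swarm of 100 agents, 500 iterations, initial gravitational coefficient
#'   100, accuracy weight 0.7, 16 gray levels, pair distances 1 and 2).
#' @keywords internal
default_config <- function() {
  list(
    phantom = list(shape = c(24, 24, 20), lesion_axes = c(8, 8, 6),
                   n_per_class = 5,
                   pos = list(mean = 100, corr_length = 1, noise_sd = 10),
                   neg = list(mean = 100, corr_length = 3, noise_sd = 10)),
    preprocess = list(sigma = 1, C = 1, levels = 16, use_log_filter = TRUE),
    extract = list(distances = c(1, 2)),
    select = list(n_agents = 100, max_iter = 500, g0 = 100, alpha = 20,
                  p = 0.8, theta = 0.7, variant = "refined", cv_folds = 5),
    classify = list(classifier = "svm", k = 5, tune = TRUE),
    seed = 1
  )
}

#' Validate a pipeline configuration file or list
#'
#' Reads a YAML file (or takes a list), fills unspecified values with the
#' defaults, warns on unknown keys and aggregates all constraint violations
#' into a single error.
#'
#' @param config Path to a YAML file, a list, or `NULL` for pure defaults.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  merged <- def
  for (blk in intersect(names(config), names(def))) {
    if (is.list(def[[blk]])) {
      unknown_k <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(unknown_k)) {
        warning(sprintf("ignoring unknown keys in `%s`: %s", blk,
                        paste(unknown_k, collapse = ", ")), call. = FALSE)
      }
      for (k in intersect(names(config[[blk]]), names(def[[blk]]))) {
        merged[[blk]][[k]] <- config[[blk]][[k]]
      }
    } else {
      merged[[blk]] <- config[[blk]]
    }
  }
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(merged$preprocess$sigma > 0, "preprocess: sigma must be > 0")
  chk(merged$preprocess$levels >= 2, "preprocess: levels must be >= 2")
  chk(merged$select$n_agents >= 2, "select: n_agents must be >= 2")
  chk(merged$select$max_iter >= 1, "select: max_iter must be >= 1")
  chk(merged$select$theta > 0 && merged$select$theta < 1,
      "select: theta must be in (0, 1)")
  chk(merged$select$p > 0 && merged$select$p <= 1,
      "select: p must be in (0, 1]")
  chk(merged$select$variant %in% c("refined", "classical"),
      "select: variant must be 'refined' or 'classical'")
  chk(merged$classify$classifier %in% c("svm", "knn"),
      "classify: classifier must be 'svm' or 'knn'")
  chk(all(merged$extract$distances >= 1), "extract: distances must be >= 1")
  chk(is.numeric(merged$seed) && length(merged$seed) == 1,
      "seed must be a single number")
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(merged, class = "pipeline_config")
}

#' Run the full phantom-to-report pipeline
#'
#' Generates (or loads) a cohort, normalizes and quantizes each volume,
#' extracts the 77-feature descriptor, selects a feature subset and SVM
#' hyperparameters with the gravitational search wrapper, and evaluates the
#' resulting classifier by leave-one-out cross-validation. By default the
#' evaluation stage re-tunes (C, sigma) on the selected features with
#' [tune_svm()] (`classify$tune = TRUE`); set it to `FALSE` to evaluate with
#' the hyperparameters decoded from the best agent.
#'
#' @param config A `pipeline_config`, list or YAML path (see
#'   [validate_config()]).
#' @param cohort Optional pre-built list of `labeled_volume` objects (e.g.
#'   from [read_cohort()]); when `NULL` a phantom cohort is generated from the
#'   config.
#' @param out_dir Optional directory; when given, the feature table (CSV), the
#'   selection (JSON) and the evaluation report (JSON) are written there.
#' @return List with `features` (tibble), `selection` (`rgsa_selection`),
#'   `report` (`eval_report`) and `config`.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE))
  }
  if (is.null(cohort)) {
    cohort <- stage("phantom", {
      spec <- phantom_spec(shape = cfg$phantom$shape,
                           lesion_axes = cfg$phantom$lesion_axes,
                           class_params = list(pos = cfg$phantom$pos,
                                               neg = cfg$phantom$neg),
                           n_per_class = cfg$phantom$n_per_class,
                           seed = cfg$seed)
      generate_cohort(spec)
    })
  }
  lp <- if (isTRUE(cfg$preprocess$use_log_filter)) {
    log_params(sigma_x = cfg$preprocess$sigma, C = cfg$preprocess$C)
  } else NULL
  features <- stage("extract", extract_cohort(
    cohort, G = cfg$preprocess$levels, distances = cfg$extract$distances,
    log_params = lp))
  sel_cfg <- rgsa_config(n_agents = cfg$select$n_agents,
                         max_iter = cfg$select$max_iter,
                         g0 = cfg$select$g0, alpha = cfg$select$alpha,
                         p = cfg$select$p, variant = cfg$select$variant)
  selection <- stage("select", rgsa_select(
    dplyr::select(features, -dplyr::all_of(c("id", "label"))),
    labels = features$label, config = sel_cfg, theta = cfg$select$theta,
    cv_folds = min(cfg$select$cv_folds, nrow(features)), seed = cfg$seed))
  Xsel <- as.matrix(features[, selection$selected, drop = FALSE])
  report <- stage("classify", if (cfg$classify$classifier == "svm") {
    hp <- if (isTRUE(cfg$classify$tune)) {
      tuned <- tune_svm(Xsel, features$label, seed = cfg$seed)
      list(C = tuned$C, sigma = tuned$sigma)
    } else {
      list(C = selection$C, sigma = selection$sigma)
    }
    loo_evaluate(Xsel, features$label, classifier = "svm",
                 C = hp$C, sigma = hp$sigma)
  } else {
    knn_baseline(Xsel, features$label, k = cfg$classify$k)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(selected = selection$selected, C = selection$C,
           sigma = selection$sigma, fitness = selection$fitness,
           history = selection$history, seed = cfg$seed),
      file.path(out_dir, "mask.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      c(as.list(glance(report)), list(seed = cfg$seed)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(features = features, selection = selection, report = report,
       config = cfg)
}
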