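#' Names of the 77-feature volumetric texture descriptor
#'
#' @return Character vector of 77 unique names: 61 `sclgm_*`, then 5 `glcm_*`,
#'   then 11 `rlm_*`.
#' @export
feature_layout <- function() {
  sclgm <- c(paste0("sclgm_pool_", profile_stat_names()),
             paste0("sclgm_line_", rep(profile_stat_names(), times = 4), "_",
                    rep(c("mean", "min", "max", "range"),
                        each = 12)),
             "sclgm_mean_line_length")
  glcm <- c("glcm_entropy", "glcm_homogeneity", "glcm_contrast",
            "glcm_energy", "glcm_correlation")
  rlm <- c("rlm_sre", "rlm_lre", "rlm_lgre", "rlm_hgre", "rlm_srlge",
           "rlm_srhge", "rlm_lrlge", "rlm_lrhge", "rlm_glnu", "rlm_rlnu",
           "rlm_rpc")
  c(sclgm, glcm, rlm)
}

#' Extract the full 77-feature texture descriptor of one region
#'
#' Co-occurrence statistics are averaged over the 13 directions and the
#' requested pair distances; run-length statistics are averaged over the 13
#' directions; the centroid-line block is appended. Directions with no valid
#' voxel pairs are skipped from the averages.
#'
#' @param voi A [quantize()]d region.
#' @param distances Integer pair distances for the co-occurrence block;
#'   values exceeding `L / 2` are dropped (at least distance 1 is kept).
#' @return A one-row tibble with 77 named feature columns, ordered as in
#'   [feature_layout()].
#' @examples
#' spec <- phantom_spec(n_per_class = 1)
#' lv <- generate_phantom(spec, label = 1, seed = 7)
#' voi <- quantize(lv$volume, lv$mask, G = 8)
#' dim(extract_features(voi))
#' @export
extract_features <- function(voi, distances = c(1, 2)) {
  stopifnot(inherits(voi, "quantized_voi"))
  distances <- unique(as.integer(distances))
  distances <- distances[distances >= 1 & distances <= max(1, voi$L / 2)]
  if (length(distances) == 0) distances <- 1L
  offs <- direction_offsets()

  glcm_acc <- NULL
  for (o in offs) for (d in distances) {
    g <- compute_glcm(voi, o, d)
    if (g$pair_count > 0) glcm_acc <- rbind(glcm_acc, glcm_features(g))
  }
  if (is.null(glcm_acc)) stop("no valid co-occurrence pairs in any direction",
                              call. = FALSE)
  glcm_block <- colMeans(glcm_acc)

  rlm_acc <- t(vapply(offs, function(o) rlm_features(compute_rlm(voi, o)),
                      numeric(11)))
  rlm_block <- colMeans(rlm_acc)

  sclgm_block <- sclgm_features(extract_centroid_lines(voi))

  out <- c(sclgm_block, glcm_block, rlm_block)
  stopifnot(identical(names(out), feature_layout()))
  tibble::as_tibble(as.list(out))
}

#' Extract the feature table of a cohort of labeled volumes
#'
#' Runs the preprocessing chain (optional LoG normalization, then gray-level
#' quantization restricted to the mask) and [extract_features()] on every
#' subject.
#'
#' @param cohort A list of `labeled_volume` objects, e.g. from
#'   [generate_cohort()].
#' @param G Number of quantization gray levels.
#' @param distances Co-occurrence pair distances.
#' @param log_params A [log_params()] object, or `NULL` to extract features
#'   from raw intensities.
#' @return A tibble with one row per subject: `id`, `label` and the 77 feature
#'   columns.
#' @export
extract_cohort <- function(cohort, G = 16, distances = c(1, 2),
                           log_params = voitex::log_params()) {
  rows <- purrr::map(cohort, function(lv) {
    stopifnot(inherits(lv, "labeled_volume"))
    vol <- lv$volume
    if (!is.null(log_params)) vol <- log_filter(vol, log_params)
    voi <- quantize(vol, lv$mask, G = G)
    dplyr::bind_cols(tibble::tibble(id = lv$id, label = lv$label),
                     extract_features(voi, distances = distances))
  })
  dplyr::bind_rows(rows)
}
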