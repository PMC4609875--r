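#' Specification of a two-class textured phantom cohort
#'
#' Describes synthetic volumes used to exercise the pipeline without clinical
#' data: an ellipsoidal lesion with class-specific texture embedded in an
#' independent-noise background. Lesion texture is Gaussian white noise
#' convolved with an isotropic Gaussian of the class correlation length, then
#' rescaled to the class mean and noise standard deviation — the smallest model
#' with a tunable co-occurrence / run-length signature.
#'
#' @param shape Voxel grid dimensions `c(nx, ny, nz)`, each at least 8.
#' @param lesion_axes Ellipsoid semi-axes in voxels; the lesion must fit
#'   inside the grid.
#' @param class_params Named list with elements `pos` and `neg` (labels +1 and
#'   -1), each a list with `mean` (base intensity), `corr_length`
#'   (Gaussian-blur standard deviation in voxels; 0 = white noise) and
#'   `noise_sd`. The two classes must differ in at least one control. Defaults
#'   give the classes identical means and noise but correlation lengths 1
#'   (label +1, rough) versus 3 (label -1, smooth).
#' @param n_per_class Subjects per class.
#' @param bg_mean,bg_sd Background noise parameters.
#' @param seed Master seed; per-subject sub-seeds are derived by counter
#'   offset.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 24, 20),
                         lesion_axes = c(8, 8, 6),
                         class_params = list(
                           pos = list(mean = 100, corr_length = 1, noise_sd = 10),
                           neg = list(mean = 100, corr_length = 3, noise_sd = 10)),
                         n_per_class = 5,
                         bg_mean = 50, bg_sd = 10,
                         seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) {
    stop("`shape` must be three dimensions, each >= 8", call. = FALSE)
  }
  if (length(lesion_axes) != 3 || any(2 * lesion_axes + 2 > shape)) {
    stop("lesion does not fit inside the grid", call. = FALSE)
  }
  for (cl in c("pos", "neg")) {
    p <- class_params[[cl]]
    if (is.null(p) || !all(c("mean", "corr_length", "noise_sd") %in% names(p))) {
      stop("`class_params` must provide mean, corr_length, noise_sd for `pos` and `neg`",
           call. = FALSE)
    }
  }
  if (identical(class_params$pos[c("mean", "corr_length", "noise_sd")],
                class_params$neg[c("mean", "corr_length", "noise_sd")])) {
    stop("the two classes must differ in at least one texture control",
         call. = FALSE)
  }
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  structure(list(shape = shape, lesion_axes = as.numeric(lesion_axes),
                 class_params = class_params,
                 n_per_class = as.integer(n_per_class),
                 bg_mean = bg_mean, bg_sd = bg_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing of a 3D array (sigma in voxels; 0 = identity)
gaussian_smooth3d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(v)
  vp <- pad_reflect(v, r)
  for (ax in 1:3) {
    out <- array(0, dim = dim(vp))
    for (s in -r:r) {
      idx <- list(seq_len(dim(vp)[1]), seq_len(dim(vp)[2]), seq_len(dim(vp)[3]))
      src <- idx
      lo <- max(1, 1 + s); hi <- min(dim(vp)[ax], dim(vp)[ax] + s)
      idx[[ax]] <- lo:hi
      src[[ax]] <- (lo:hi) - s
      out[idx[[1]], idx[[2]], idx[[3]]] <-
        out[idx[[1]], idx[[2]], idx[[3]]] +
        k[s + r + 1] * vp[src[[1]], src[[2]], src[[3]]]
    }
    vp <- out
  }
  vp[(r + 1):(d[1] + r), (r + 1):(d[2] + r), (r + 1):(d[3] + r)]
}

ellipsoid_mask <- function(shape, axes, center = (shape + 1) / 2) {
  x <- (seq_len(shape[1]) - center[1]) / axes[1]
  y <- (seq_len(shape[2]) - center[2]) / axes[2]
  z <- (seq_len(shape[3]) - center[3]) / axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate one labeled phantom volume
#'
#' @param spec A [phantom_spec()].
#' @param label Class label, `+1` or `-1`.
#' @param seed RNG seed for this subject.
#' @param id Subject identifier stored with the volume.
#' @return An object of class `labeled_volume`: `volume` (numeric 3D array),
#'   `mask` (logical array of the lesion), `label` and `id`.
#' @export
generate_phantom <- function(spec, label, seed, id = sprintf("s%04d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"), label %in% c(-1, 1))
  cp <- spec$class_params[[if (label > 0) "pos" else "neg"]]
  mask <- ellipsoid_mask(spec$shape, spec$lesion_axes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vol <- array(rnorm(prod(spec$shape), spec$bg_mean, spec$bg_sd),
               dim = spec$shape)
  if (cp$noise_sd > 0) {
    field <- array(rnorm(prod(spec$shape)), dim = spec$shape)
    field <- gaussian_smooth3d(field, cp$corr_length)
    field <- (field - mean(field)) / sd(field)  # unit-variance texture field
    vol[mask] <- cp$mean + cp$noise_sd * field[mask]
  } else {
    vol[mask] <- cp$mean
  }
  structure(list(volume = vol, mask = mask, label = as.integer(label), id = id),
            class = "labeled_volume")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a balanced phantom cohort
#'
#' One subject per sub-seed, alternating labels; sub-seeds are derived from
#' the master seed by counter offset so cohorts of any size are reproducible.
#'
#' @param spec A [phantom_spec()].
#' @return List of `2 * n_per_class` `labeled_volume` objects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_per_class
  labels <- rep(c(1L, -1L), each = n)
  purrr::map(seq_along(labels), function(i) {
    generate_phantom(spec, labels[i], seed = spec$seed * 1000L + i,
                     id = sprintf("s%03d_%s", i,
                                  if (labels[i] > 0) "pos" else "neg"))
  })
}

#' Generate a labeled tabular dataset with a known informative subset
#'
#' Class-conditional Gaussian features: `k` informative columns have their
#' class means separated by `effect` noise standard deviations; the remaining
#' columns are identically distributed in both classes. This is the controlled
#' test bed for wrapper feature selection.
#'
#' @param n Total samples (balanced classes).
#' @param d Feature dimension.
#' @param k Number of informative features, `k <= d`.
#' @param effect Class-mean separation on informative columns, in units of the
#'   unit noise standard deviation.
#' @param seed RNG seed.
#' @return An object of class `tabular_dataset`: `features` (n x d tibble with
#'   columns `f1..fd`), `labels` (+1/-1 integer vector), `informative_idx` and
#'   `seed`.
#' @export
generate_tabular <- function(n = 60, d = 77, k = 10, effect = 2, seed = 1) {
  if (k > d) stop("`k` must not exceed `d`", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labels <- rep(c(1L, -1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  informative <- sort(sample.int(d, k))
  X[, informative] <- X[, informative] + (effect / 2) * labels
  colnames(X) <- paste0("f", seq_len(d))
  structure(list(features = tibble::as_tibble(as.data.frame(X)),
                 labels = labels, informative_idx = informative,
                 seed = as.integer(seed)),
            class = "tabular_dataset")
}

#' Write a phantom cohort to NIfTI files with a CSV manifest
#'
#' @param cohort List of `labeled_volume` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`id`, `label`, `volume`, `mask`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(cohort, function(lv) {
    vpath <- file.path(dir, paste0(lv$id, "_vol.nii.gz"))
    mpath <- file.path(dir, paste0(lv$id, "_mask.nii.gz"))
    RNifti::writeNifti(lv$volume, vpath)
    RNifti::writeNifti(array(as.numeric(lv$mask), dim = dim(lv$mask)), mpath)
    tibble::tibble(id = lv$id, label = lv$label, volume = vpath, mask = mpath)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List of `labeled_volume` objects.
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(man)), function(i) {
    strip <- function(a) array(as.numeric(a), dim = dim(a))
    vol <- tryCatch(strip(as.array(RNifti::readNifti(man$volume[i]))),
                    error = function(e) stop(sprintf(
                      "preprocess stage: cannot read volume '%s': %s",
                      man$volume[i], conditionMessage(e)), call. = FALSE))
    msk <- strip(as.array(RNifti::readNifti(man$mask[i]))) > 0.5
    structure(list(volume = vol, mask = msk,
                   label = as.integer(man$label[i]), id = man$id[i]),
              class = "labeled_volume")
  })
}
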