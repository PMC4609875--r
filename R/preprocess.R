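#' Laplacian-of-Gaussian filter parameters
#'
#' The 3D LoG ("Mexican hat") filter used to normalize volumes before texture
#' extraction. The kernel at displacement (x, y, z) from its center is
#' \deqn{C\left[\left(\frac{x^2}{\sigma_x^4}-\frac{1}{\sigma_x^2}\right)+
#'   \left(\frac{y^2}{\sigma_y^4}-\frac{1}{\sigma_y^2}\right)+
#'   \left(\frac{z^2}{\sigma_z^4}-\frac{1}{\sigma_z^2}\right)\right]
#'   e^{-x^2/2\sigma_x^2-y^2/2\sigma_y^2-z^2/2\sigma_z^2}.}
#'
#' @param sigma_x,sigma_y,sigma_z Kernel standard deviations in voxels; all
#'   must be positive. `sigma_y`/`sigma_z` default to `sigma_x`.
#' @param C Scalar gain applied to the kernel.
#' @param kernel_radius Truncation half-width in voxels; must be at least
#'   3 times the largest sigma. Defaults to `ceiling(4 * max(sigma))`.
#' @return An object of class `log_params`.
#' @export
log_params <- function(sigma_x = 1, sigma_y = sigma_x, sigma_z = sigma_x,
                       C = 1, kernel_radius = NULL) {
  if (any(c(sigma_x, sigma_y, sigma_z) <= 0)) {
    stop("all kernel standard deviations must be positive", call. = FALSE)
  }
  if (is.null(kernel_radius)) {
    kernel_radius <- ceiling(4 * max(sigma_x, sigma_y, sigma_z))
  }
  if (kernel_radius < 3 * max(sigma_x, sigma_y, sigma_z)) {
    stop("`kernel_radius` must be >= 3 * max(sigma)", call. = FALSE)
  }
  structure(
    list(sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
         C = C, kernel_radius = as.integer(kernel_radius)),
    class = "log_params"
  )
}

#' Discrete 3D Laplacian-of-Gaussian kernel
#'
#' Evaluates the LoG expression on the integer grid
#' `[-kernel_radius, kernel_radius]^3`. The continuous LoG integrates to zero;
#' truncation breaks this, so by default the discrete kernel is mean-subtracted
#' to restore a zero response to constant inputs.
#'
#' @param params A [log_params()] object.
#' @param dc_correct Subtract the kernel mean after truncation (default TRUE).
#' @return A numeric 3D array of odd side length `2 * kernel_radius + 1`.
#' @examples
#' k <- log_kernel(log_params(sigma_x = 1), dc_correct = FALSE)
#' k[5, 5, 5]  # center value at unit sigma, C = 1: -3
#' @export
log_kernel <- function(params = log_params(), dc_correct = TRUE) {
  stopifnot(inherits(params, "log_params"))
  r <- params$kernel_radius
  g <- seq(-r, r)
  sx <- params$sigma_x; sy <- params$sigma_y; sz <- params$sigma_z
  x <- array(rep(g, times = (2 * r + 1)^2), dim = rep(2 * r + 1, 3))
  y <- aperm(x, c(2, 1, 3))
  z <- aperm(x, c(3, 2, 1))
  poly <- (x^2 / sx^4 - 1 / sx^2) + (y^2 / sy^4 - 1 / sy^2) +
    (z^2 / sz^4 - 1 / sz^2)
  k <- params$C * poly * exp(-x^2 / (2 * sx^2) - y^2 / (2 * sy^2) -
                               z^2 / (2 * sz^2))
  if (dc_correct) k <- k - mean(k)
  k
}

# reflect-pad a 3D array by r voxels on every face
pad_reflect <- function(v, r) {
  d <- dim(v)
  ix <- lapply(d, function(n) {
    if (r >= n) stop("kernel larger than volume", call. = FALSE)
    c(seq(r, 1), seq_len(n), seq(n, n - r + 1))
  })
  v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Apply the 3D LoG filter to a volume
#'
#' Discrete convolution of the (even-symmetric) LoG kernel with the volume,
#' with reflected boundaries; the output has the same dimensions as the input.
#'
#' @param volume A numeric 3D array.
#' @param params A [log_params()] object.
#' @param dc_correct Passed to [log_kernel()].
#' @return Filtered volume, same shape as `volume`.
#' @export
log_filter <- function(volume, params = log_params(), dc_correct = TRUE) {
  stop_if_not_volume(volume)
  k <- log_kernel(params, dc_correct = dc_correct)
  r <- params$kernel_radius
  vp <- pad_reflect(volume, r)
  d <- dim(volume)
  out <- array(0, dim = d)
  # accumulate one shifted copy per kernel tap; the kernel is even in each
  # axis so convolution and correlation coincide
  for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
    w <- k[a + r + 1, b + r + 1, cc + r + 1]
    if (w == 0) next
    out <- out + w * vp[(1 + r + a):(d[1] + r + a),
                        (1 + r + b):(d[2] + r + b),
                        (1 + r + cc):(d[3] + r + cc)]
  }
  out
}

#' Quantize the in-mask intensities of a volume
#'
#' Min-max linear binning of the intensities under the mask into gray levels
#' `1..G`. Voxels outside the mask are set to `NA`. If the in-mask intensity is
#' constant, every voxel maps to level 1.
#'
#' @param volume A numeric 3D array.
#' @param mask A logical (or 0/1) array of the same shape; must select at
#'   least one voxel.
#' @param G Number of gray levels, at least 2 (default 16).
#' @return An object of class `quantized_voi` with elements `levels` (integer
#'   array, `NA` outside the mask), `mask`, `G`, `L` (longest bounding-box edge
#'   in voxels) and `n_voxels`.
#' @examples
#' v <- array(runif(4^3), dim = c(4, 4, 4))
#' m <- array(TRUE, dim = c(4, 4, 4))
#' q <- quantize(v, m, G = 8)
#' range(q$levels)
#' @export
quantize <- function(volume, mask, G = 16) {
  stop_if_not_volume(volume)
  stop_if_not_mask(mask, volume)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("`mask` selects no voxels", call. = FALSE)
  if (G < 2) stop("`G` must be at least 2", call. = FALSE)
  vals <- volume[mask]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim = dim(volume))
  if (hi > lo) {
    q <- floor((volume[mask] - lo) / (hi - lo) * G) + 1L
    lev[mask] <- as.integer(pmin(q, G))
  } else {
    lev[mask] <- 1L
  }
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  L <- max(bb[2, ] - bb[1, ] + 1L)
  structure(
    list(levels = lev, mask = mask, G = as.integer(G), L = as.integer(L),
         n_voxels = sum(mask)),
    class = "quantized_voi"
  )
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat(sprintf("<quantized_voi> %d voxels, G = %d levels, L = %d, grid %s\n",
              x$n_voxels, x$G, x$L, paste(dim(x$mask), collapse = "x")))
  invisible(x)
}
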