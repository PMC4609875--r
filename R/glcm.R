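#' Gray-level co-occurrence matrix along one direction
#'
#' Counts pairs of quantized gray levels `(g(v), g(v + d * offset))` where both
#' voxels lie inside the mask, symmetrizes (each pair counted in both orders)
#' and normalizes to a probability matrix.
#'
#' @param voi A [quantize()]d region.
#' @param offset Integer displacement vector `c(dx, dy, dz)`, typically a row
#'   of [direction_table()].
#' @param d Integer pair distance; must satisfy `1 <= d <= L / 2` where `L` is
#'   the region's longest bounding-box edge.
#' @return An object of class `glcm`: list with `P` (GxG matrix summing to 1
#'   when pairs exist), `offset`, `d` and `pair_count` (raw directed pairs).
#' @examples
#' v <- array(c(1, 2, 1), dim = c(1, 3, 1))
#' q <- quantize(v, array(TRUE, dim = c(1, 3, 1)), G = 2)
#' compute_glcm(q, c(0, 1, 0), d = 1)$P
#' @export
compute_glcm <- function(voi, offset, d = 1) {
  stopifnot(inherits(voi, "quantized_voi"), length(offset) == 3)
  if (d < 1 || d > voi$L / 2) {
    stop(sprintf("`d` must be in [1, L/2] = [1, %g]", voi$L / 2), call. = FALSE)
  }
  G <- voi$G
  dims <- dim(voi$levels)
  sh <- as.integer(d * offset)
  # index ranges of source voxels whose shifted partner stays in the grid
  rng <- lapply(1:3, function(ax) {
    s <- sh[ax]
    lo <- max(1L, 1L - s); hi <- min(dims[ax], dims[ax] - s)
    if (lo > hi) NULL else lo:hi
  })
  M <- matrix(0, G, G)
  pair_count <- 0L
  if (!any(vapply(rng, is.null, logical(1)))) {
    g1 <- voi$levels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    g2 <- voi$levels[rng[[1]] + sh[1], rng[[2]] + sh[2], rng[[3]] + sh[3],
                     drop = FALSE]
    ok <- !is.na(g1) & !is.na(g2)
    pair_count <- sum(ok)
    if (pair_count > 0) {
      idx <- cbind(g1[ok], g2[ok])
      for (r in seq_len(nrow(idx))) M[idx[r, 1], idx[r, 2]] <-
          M[idx[r, 1], idx[r, 2]] + 1
    }
  }
  P <- M + t(M)
  if (pair_count > 0) P <- P / sum(P)
  structure(list(P = P, offset = as.integer(offset), d = as.integer(d),
                 pair_count = as.integer(pair_count)),
            class = "glcm")
}

#' Haralick statistics of a co-occurrence matrix
#'
#' Entropy (bits), homogeneity, contrast, energy and correlation of a
#' normalized, symmetric co-occurrence matrix. Correlation uses the mean and
#' variance of the (single, symmetric) marginal; a degenerate marginal with
#' zero variance yields correlation 0.
#'
#' @param glcm A `glcm` object from [compute_glcm()], or a normalized matrix.
#' @return A named numeric vector of length 5:
#'   `glcm_entropy`, `glcm_homogeneity`, `glcm_contrast`, `glcm_energy`,
#'   `glcm_correlation`.
#' @export
glcm_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  if (inherits(glcm, "glcm") && glcm$pair_count == 0) {
    stop("co-occurrence matrix has no pairs", call. = FALSE)
  }
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  homogeneity <- sum(P / (1 + abs(i - j)))
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  marg <- rowSums(P)
  mu <- sum(seq_len(G) * marg)
  s2 <- sum((seq_len(G) - mu)^2 * marg)
  correlation <- if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 0
  c(glcm_entropy = entropy, glcm_homogeneity = homogeneity,
    glcm_contrast = contrast, glcm_energy = energy,
    glcm_correlation = correlation)
}
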