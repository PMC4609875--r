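#' Gray-level run-length matrix along one direction
#'
#' Decomposes the voxel grid into lattice lines parallel to `offset` and counts
#' maximal runs of equal quantized gray level along each line, restricted to
#' in-mask voxels. Out-of-mask voxels break runs.
#'
#' @param voi A [quantize()]d region.
#' @param offset Integer unit displacement `c(dx, dy, dz)` with components in
#'   \{-1, 0, 1\}, not all zero.
#' @return An object of class `rlm`: `p` (G x Nmax count matrix, gray level by
#'   run length), `nr` (total runs) and `offset`.
#' @examples
#' v <- array(c(1, 1, 2, 2), dim = c(1, 4, 1))
#' q <- quantize(v, array(TRUE, dim = c(1, 4, 1)), G = 2)
#' compute_rlm(q, c(0, 1, 0))$p
#' @export
compute_rlm <- function(voi, offset) {
  stopifnot(inherits(voi, "quantized_voi"), length(offset) == 3)
  offset <- as.integer(offset)
  if (all(offset == 0) || any(abs(offset) > 1)) {
    stop("`offset` must be a nonzero unit step in each axis", call. = FALSE)
  }
  if (voi$n_voxels == 0) stop("empty VOI", call. = FALSE)
  dims <- dim(voi$levels)
  co <- which(array(TRUE, dims), arr.ind = TRUE)  # all grid voxels
  # parametrize each lattice line: t advances by +1 per step along `offset`
  ax <- which(offset != 0)[1]
  t_par <- co[, ax] * offset[ax]
  base <- co - t_par %*% t(offset)                # line anchor, constant per line
  md <- max(dims)
  b <- base + md                                   # strictly positive anchors
  K1 <- dims[1] + 2 * md + 1
  K2 <- dims[2] + 2 * md + 1
  lid <- b[, 1] + K1 * (b[, 2] + K2 * b[, 3])
  ord <- order(lid, t_par)
  lv <- as.vector(voi$levels)[ord]
  lid <- lid[ord]
  n <- length(lv)
  same_line <- c(FALSE, lid[-1] == lid[-n])
  same_lv <- c(FALSE, !is.na(lv[-1]) & !is.na(lv[-n]) & lv[-1] == lv[-n])
  new_run <- !(same_line & same_lv)
  run_id <- cumsum(new_run)
  keep <- !is.na(lv)
  if (!any(keep)) stop("empty VOI", call. = FALSE)
  run_len <- tapply(keep[keep], run_id[keep], length)
  run_lev <- lv[keep][!duplicated(run_id[keep])]
  Nmax <- max(run_len)
  p <- matrix(0, voi$G, Nmax)
  for (r in seq_along(run_len)) {
    p[run_lev[r], run_len[r]] <- p[run_lev[r], run_len[r]] + 1
  }
  structure(list(p = p, nr = length(run_len), offset = offset), class = "rlm")
}

#' Run-length texture statistics
#'
#' The 11 classical run-length statistics: short/long run emphasis, low/high
#' gray-level run emphasis, their four joint variants, gray-level and
#' run-length nonuniformity, and run percentage (runs per covered voxel).
#'
#' @param rlm An `rlm` object from [compute_rlm()].
#' @return Named numeric vector of length 11 (`rlm_sre`, `rlm_lre`,
#'   `rlm_lgre`, `rlm_hgre`, `rlm_srlge`, `rlm_srhge`, `rlm_lrlge`,
#'   `rlm_lrhge`, `rlm_glnu`, `rlm_rlnu`, `rlm_rpc`).
#' @export
rlm_features <- function(rlm) {
  stopifnot(inherits(rlm, "rlm"))
  p <- rlm$p
  nr <- rlm$nr
  if (nr == 0) stop("run-length matrix has no runs", call. = FALSE)
  M <- nrow(p); N <- ncol(p)
  i2 <- matrix(seq_len(M)^2, M, N)
  j2 <- matrix(rep(seq_len(N)^2, each = M), M, N)
  jj <- matrix(rep(seq_len(N), each = M), M, N)
  c(rlm_sre   = sum(p / j2) / nr,
    rlm_lre   = sum(p * j2) / nr,
    rlm_lgre  = sum(p / i2) / nr,
    rlm_hgre  = sum(p * i2) / nr,
    rlm_srlge = sum(p / (i2 * j2)) / nr,
    rlm_srhge = sum(p * i2 / j2) / nr,
    rlm_lrlge = sum(p * j2 / i2) / nr,
    rlm_lrhge = sum(p * i2 * j2) / nr,
    rlm_glnu  = sum(rowSums(p)^2) / nr,
    rlm_rlnu  = sum(colSums(p)^2) / nr,
    rlm_rpc   = nr / sum(p * jj))
}
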