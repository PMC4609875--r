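#' The 13 unique displacement directions of a 3D voxel neighborhood
#'
#' A voxel has 26 neighbors; taking one displacement from each antipodal pair
#' leaves 13 unique directions. Co-occurrence and run-length statistics are
#' accumulated along each of these, and the centroid-line profiles are drawn
#' through the region centroid along the same orientations.
#'
#' @return A tibble with 13 rows and columns `id`, `dx`, `dy`, `dz` (integer
#'   voxel offsets) and `theta`, `phi` (orientation angles in degrees).
#' @examples
#' direction_table()
#' @export
direction_table <- function() {
  tibble::tibble(
    id = 1:13,
    dx = c(0L, -1L, -1L, -1L, 0L, 0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L),
    dy = c(1L, 1L, 0L, -1L, 1L, 0L, -1L, 0L, 0L, 1L, -1L, -1L, 1L),
    dz = c(0L, 0L, 0L, 0L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L),
    theta = c(0, 45, 90, 135, 0, 0, 0, 90, 90, 45, 45, 135, 135),
    phi   = c(0, 0, 0, 0, 45, 90, 135, 45, 135, 45, 135, 45, 135)
  )
}

direction_offsets <- function() {
  tab <- direction_table()
  lapply(seq_len(nrow(tab)), function(i) c(tab$dx[i], tab$dy[i], tab$dz[i]))
}
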