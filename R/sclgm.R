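#' Gray-level profiles along the 13 centroid lines of a region
#'
#' The region centroid is the mean in-mask voxel coordinate, rounded to the
#' nearest voxel (ties toward the lower index). For each of the 13 unique
#' neighborhood orientations a maximal digital ray is traced through the
#' centroid in both directions (`+offset` and `-offset`), clipped to the voxel
#' grid; the profile is the ordered sequence of in-mask gray levels along it.
#'
#' @param voi A [quantize()]d region.
#' @return An object of class `centroid_lines`: `lines` (list of 13 integer
#'   profiles, ordered from the negative to the positive end of the ray),
#'   `centroid` (rounded voxel coordinate), `centroid_raw` (mean coordinate)
#'   and `line_lengths` (in-mask voxel counts).
#' @export
extract_centroid_lines <- function(voi) {
  stopifnot(inherits(voi, "quantized_voi"))
  if (voi$n_voxels == 0) stop("empty VOI", call. = FALSE)
  dims <- dim(voi$levels)
  co <- which(voi$mask, arr.ind = TRUE)
  cen_raw <- colMeans(co)
  cen <- ceiling(cen_raw - 0.5)  # round half toward the lower index
  cen <- pmin(pmax(cen, 1), dims)
  offs <- direction_offsets()
  lines <- lapply(offs, function(o) {
    # max parameter value keeping every moving axis inside the grid
    t_lim <- function(dirn) {
      lim <- Inf
      for (ax in 1:3) {
        if (dirn[ax] > 0) lim <- min(lim, dims[ax] - cen[ax])
        if (dirn[ax] < 0) lim <- min(lim, cen[ax] - 1)
      }
      if (!is.finite(lim)) 0 else lim
    }
    t_neg <- t_lim(-o); t_pos <- t_lim(o)
    ts <- seq(-t_neg, t_pos)
    pts <- cbind(cen[1] + ts * o[1], cen[2] + ts * o[2], cen[3] + ts * o[3])
    lv <- voi$levels[pts]
    as.integer(lv[!is.na(lv)])
  })
  structure(list(lines = lines, centroid = as.integer(cen),
                 centroid_raw = cen_raw,
                 line_lengths = vapply(lines, length, integer(1))),
            class = "centroid_lines")
}

# 12 distribution statistics of one gray-level profile.
# Moments use population (1/n) normalization; skewness and excess kurtosis of a
# zero-variance profile are 0 by convention. Energy and entropy are computed on
# the normalized histogram of the profile's gray levels.
profile_stats <- function(x) {
  n <- length(x)
  if (n == 0) {
    return(stats::setNames(rep(NA_real_, 12), profile_stat_names()))
  }
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 - 3 else 0
  p <- as.numeric(table(x)) / n
  c(mean = m,
    variance = v,
    mad = mean(abs(x - m)),
    sd = s,
    skewness = skew,
    kurtosis = kurt,
    median = stats::median(x),
    min = min(x),
    max = max(x),
    range = diff(range(x)),
    energy = sum(p^2),
    entropy = -sum(p * log2(p)))
}

profile_stat_names <- function() {
  c("mean", "variance", "mad", "sd", "skewness", "kurtosis",
    "median", "min", "max", "range", "energy", "entropy")
}

#' Centroid-line gray-level distribution features
#'
#' The 61-value SCLGM block: 12 distribution statistics of the pooled gray
#' levels of all 13 centroid lines; the same 12 statistics computed per line
#' and aggregated across lines by mean, min, max and range (48 values); plus
#' the mean line length (1 value). Empty profiles (possible for very thin
#' regions) are excluded from the per-line aggregation and contribute length 0.
#'
#' @param lines A `centroid_lines` object from [extract_centroid_lines()].
#' @return Named numeric vector of length 61, names prefixed `sclgm_`.
#' @export
sclgm_features <- function(lines) {
  stopifnot(inherits(lines, "centroid_lines"))
  pooled <- unlist(lines$lines)
  if (length(pooled) == 0) stop("all centroid lines are empty", call. = FALSE)
  pool <- profile_stats(pooled)
  names(pool) <- paste0("sclgm_pool_", names(pool))
  per <- vapply(lines$lines[lines$line_lengths > 0], profile_stats,
                numeric(12))
  agg <- c(
    stats::setNames(rowMeans(per), paste0("sclgm_line_",
                                          profile_stat_names(), "_mean")),
    stats::setNames(apply(per, 1, min), paste0("sclgm_line_",
                                               profile_stat_names(), "_min")),
    stats::setNames(apply(per, 1, max), paste0("sclgm_line_",
                                               profile_stat_names(), "_max")),
    stats::setNames(apply(per, 1, max) - apply(per, 1, min),
                    paste0("sclgm_line_", profile_stat_names(), "_range"))
  )
  c(pool, agg, sclgm_mean_line_length = mean(lines$line_lengths))
}
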