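# Brute-force oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (triple loops, pair enumeration) and
# independent of the package's vectorized implementations.

make_random_voi <- function(dims = c(5, 5, 5), G = 4, density = 0.7,
                            seed = 1) {
  set.seed(seed)
  vol <- array(runif(prod(dims)), dim = dims)
  mask <- array(runif(prod(dims)) < density, dim = dims)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  quantize(vol, mask, G = G)
}

# ordered-pair counts by exhaustive voxel enumeration
brute_glcm <- function(voi, offset, d) {
  dims <- dim(voi$levels)
  G <- voi$G
  M <- matrix(0, G, G)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    g1 <- voi$levels[x, y, z]
    if (is.na(g1)) next
    tx <- x + d * offset[1]; ty <- y + d * offset[2]; tz <- z + d * offset[3]
    if (tx < 1 || tx > dims[1] || ty < 1 || ty > dims[2] ||
        tz < 1 || tz > dims[3]) next
    g2 <- voi$levels[tx, ty, tz]
    if (is.na(g2)) next
    M[g1, g2] <- M[g1, g2] + 1
  }
  M
}

# run counts by walking every lattice line voxel by voxel
brute_rlm <- function(voi, offset) {
  dims <- dim(voi$levels)
  runs <- list()
  visited <- array(FALSE, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    # start of a line: stepping backwards leaves the grid
    px <- x - offset[1]; py <- y - offset[2]; pz <- z - offset[3]
    if (px >= 1 && px <= dims[1] && py >= 1 && py <= dims[2] &&
        pz >= 1 && pz <= dims[3]) next
    cx <- x; cy <- y; cz <- z
    cur_lev <- NA; cur_len <- 0
    while (cx >= 1 && cx <= dims[1] && cy >= 1 && cy <= dims[2] &&
           cz >= 1 && cz <= dims[3]) {
      g <- voi$levels[cx, cy, cz]
      if (is.na(g)) {
        if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- NA; cur_len <- 0
      } else if (!is.na(cur_lev) && g == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- g; cur_len <- 1
      }
      cx <- cx + offset[1]; cy <- cy + offset[2]; cz <- cz + offset[3]
    }
    if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (length(runs) == 0) return(matrix(0, voi$G, 1))
  rr <- do.call(rbind, runs)
  p <- matrix(0, voi$G, max(rr[, 2]))
  for (i in seq_len(nrow(rr))) p[rr[i, 1], rr[i, 2]] <- p[rr[i, 1], rr[i, 2]] + 1
  p
}

# AUC as the Mann-Whitney probability that a positive outranks a negative
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# one classical-GSA iteration computed by explicit pairwise loops
brute_gsa_iteration <- function(X, V, fit, G, xi, kbest_idx, r, rand_i) {
  N <- nrow(X); n <- ncol(X)
  best <- min(fit); worst <- max(fit)
  m <- (fit - worst) / (best - worst)
  M <- m / sum(m)
  Fm <- matrix(0, N, n)
  for (i in 1:N) for (j in kbest_idx) {
    if (j == i) next
    R <- sqrt(sum((X[i, ] - X[j, ])^2))
    for (d in 1:n) {
      Fm[i, d] <- Fm[i, d] +
        r[i, j] * G * M[i] * M[j] / (R + xi) * (X[j, d] - X[i, d])
    }
  }
  a <- matrix(0, N, n)
  for (i in 1:N) if (M[i] > 0) a[i, ] <- Fm[i, ] / M[i]
  Vn <- rand_i * V + a
  Xn <- pmin(pmax(X + Vn, 0), 1)
  list(M = M, force = Fm, velocities = Vn, positions = Xn)
}
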