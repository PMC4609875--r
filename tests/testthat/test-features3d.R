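test_that("direction table covers the 26-neighborhood without antipodal pairs", {
  tab <- direction_table()
  expect_equal(nrow(tab), 13)
  expect_equal(unlist(tab[1, c("dx", "dy", "dz")], use.names = FALSE),
               c(0L, 1L, 0L))
  expect_equal(unlist(tab[13, c("dx", "dy", "dz")], use.names = FALSE),
               c(1L, 1L, -1L))
  offs <- as.matrix(tab[, c("dx", "dy", "dz")])
  keys <- apply(rbind(offs, -offs), 1, paste, collapse = ",")
  expect_equal(length(unique(keys)), 26)  # no offset is another's negation
  all26 <- expand.grid(-1:1, -1:1, -1:1)
  all26 <- all26[rowSums(abs(all26)) > 0, ]
  expect_setequal(keys, apply(all26, 1, paste, collapse = ","))
})

test_that("co-occurrence pairs match hand enumeration and the brute-force oracle", {
  v <- array(c(1, 2, 1), dim = c(1, 3, 1))
  q <- quantize(v, array(TRUE, dim = c(1, 3, 1)), G = 2)
  g <- compute_glcm(q, c(0, 1, 0), d = 1)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(sum(g$P), 1)

  const <- quantize(array(1, dim = c(3, 3, 3)), array(TRUE, dim = c(3, 3, 3)),
                    G = 4)
  gc <- compute_glcm(const, c(1, 0, 0), 1)
  expect_equal(sum(gc$P > 0), 1)
  expect_equal(gc$P[1, 1], 1)

  offs <- voitex:::direction_offsets()
  for (s in 1:34) {
    voi <- make_random_voi(seed = s, G = 4, density = 0.6)
    for (o in offs[c(1, 6, 10, 13)]) {
      got <- compute_glcm(voi, o, 1)
      M <- brute_glcm(voi, o, 1)
      expect_equal(got$pair_count, sum(M))
      if (sum(M) > 0) expect_equal(got$P, (M + t(M)) / sum(M + t(M)))
    }
  }
})

test_that("co-occurrence statistics match hand-computed closed forms", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f <- glcm_features(P)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_energy"]), 0.5)
  expect_equal(unname(f["glcm_homogeneity"]), 0.5)
  expect_equal(unname(f["glcm_correlation"]), -1)
  expect_equal(unname(f["glcm_entropy"]), 1)

  one <- matrix(0, 3, 3); one[2, 2] <- 1
  f1 <- glcm_features(one)
  expect_equal(unname(f1["glcm_energy"]), 1)
  expect_equal(unname(f1["glcm_contrast"]), 0)
  expect_equal(unname(f1["glcm_entropy"]), 0)
  expect_equal(unname(f1["glcm_correlation"]), 0)  # degenerate marginal

  unif <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2)
  expect_equal(unname(glcm_features(unif)["glcm_entropy"]), 2)
})

test_that("run-length counts match hand enumeration and conserve voxels", {
  v <- array(c(1, 1, 2, 2), dim = c(1, 4, 1))
  q <- quantize(v, array(TRUE, dim = c(1, 4, 1)), G = 2)
  r <- compute_rlm(q, c(0, 1, 0))
  expect_equal(r$nr, 2)
  expect_equal(r$p[1, 2], 1)
  expect_equal(r$p[2, 2], 1)

  const <- quantize(array(2, dim = c(1, 5, 1)), array(TRUE, dim = c(1, 5, 1)),
                    G = 3)
  rc <- compute_rlm(const, c(0, 1, 0))
  expect_equal(rc$nr, 1)
  expect_equal(rc$p[1, 5], 1)

  offs <- voitex:::direction_offsets()
  for (s in 35:68) {
    voi <- make_random_voi(seed = s, G = 3, density = 0.65)
    for (o in offs[c(1, 3, 6, 11, 13)]) {
      got <- compute_rlm(voi, o)
      oracle <- brute_rlm(voi, o)
      expect_equal(got$p, oracle)
      # every in-mask voxel belongs to exactly one run
      expect_equal(sum(sweep(got$p, 2, seq_len(ncol(got$p)), `*`)),
                   voi$n_voxels)
    }
  }
})

test_that("run-length statistics match Table substitutions and scale invariance", {
  mk <- function(p, nr) structure(list(p = p, nr = nr, offset = c(0, 1, 0)),
                                  class = "rlm")
  p <- matrix(0, 2, 2); p[1, 2] <- 1; p[2, 2] <- 1
  f <- rlm_features(mk(p, 2))
  expect_equal(unname(f["rlm_sre"]), 0.25)
  expect_equal(unname(f["rlm_lre"]), 4)

  single <- matrix(0, 2, 1); single[1, 1] <- 1
  fs <- rlm_features(mk(single, 1))
  expect_equal(unname(fs["rlm_sre"]), 1)
  expect_equal(unname(fs["rlm_lre"]), 1)
  expect_equal(unname(fs["rlm_rpc"]), 1)

  f2 <- rlm_features(mk(2 * p, 4))
  expect_equal(f["rlm_sre"], f2["rlm_sre"])
  expect_equal(f["rlm_lrhge"], f2["rlm_lrhge"])
})

test_that("centroid lines pass through the centroid and are translation invariant", {
  mask <- array(FALSE, dim = c(15, 15, 15))
  mask[4:12, 4:12, 5:11] <- TRUE
  set.seed(8)
  vol <- array(runif(15^3), dim = c(15, 15, 15))
  voi <- quantize(vol, mask, G = 4)
  cl <- extract_centroid_lines(voi)
  expect_equal(cl$centroid, c(8L, 8L, 8L))
  expect_length(cl$lines, 13)
  expect_true(all(cl$line_lengths > 0))

  # translate volume and mask by (2, 1, 3): profiles unchanged
  mask2 <- array(FALSE, dim = c(18, 17, 19))
  mask2[6:14, 5:13, 8:14] <- TRUE
  vol2 <- array(0, dim = c(18, 17, 19))
  vol2[6:14, 5:13, 8:14] <- vol[4:12, 4:12, 5:11]
  voi2 <- quantize(vol2, mask2, G = 4)
  cl2 <- extract_centroid_lines(voi2)
  expect_equal(cl$lines, cl2$lines)
})

test_that("near-spherical regions give near-equal line lengths", {
  spec <- phantom_spec(shape = c(25, 25, 25), lesion_axes = c(9, 9, 9),
                       n_per_class = 1)
  lv <- generate_phantom(spec, 1, seed = 2)
  voi <- quantize(lv$volume, lv$mask, G = 8)
  cl <- extract_centroid_lines(voi)
  # diagonal rays advance by steps of length sqrt(2) or sqrt(3), so compare
  # geometric lengths (voxel count x step length), which digitization keeps
  # within a couple of voxels of each other on a sphere
  step_len <- vapply(voitex:::direction_offsets(),
                     function(o) sqrt(sum(o^2)), numeric(1))
  geom_len <- cl$line_lengths * step_len
  expect_lte(diff(range(geom_len)), 4)
})

test_that("profile statistics follow the moment conventions", {
  ps <- voitex:::profile_stats(c(5, 5, 5))
  expect_equal(unname(ps[c("mean", "variance", "sd", "mad",
                           "skewness", "kurtosis")]),
               c(5, 0, 0, 0, 0, 0))
  p2 <- voitex:::profile_stats(c(1, 2, 3))
  expect_equal(unname(p2["mean"]), 2)
  expect_equal(unname(p2["variance"]), 2 / 3)
  expect_equal(unname(p2["mad"]), 2 / 3)
  expect_equal(unname(p2["range"]), 2)
  expect_equal(unname(p2["entropy"]), log2(3))
})

test_that("the full descriptor has the documented layout and is deterministic", {
  spec <- phantom_spec(n_per_class = 1)
  lv <- generate_phantom(spec, 1, seed = 13)
  voi <- quantize(lv$volume, lv$mask, G = 8)
  fv <- extract_features(voi)
  expect_equal(ncol(fv), 77)
  expect_identical(names(fv), feature_layout())
  expect_equal(sum(grepl("^sclgm_", names(fv))), 61)
  expect_equal(sum(grepl("^glcm_", names(fv))), 5)
  expect_equal(sum(grepl("^rlm_", names(fv))), 11)
  expect_identical(fv, extract_features(voi))
})
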