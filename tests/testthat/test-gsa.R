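test_that("gravitational coefficient decays exponentially from G0", {
  cfg <- rgsa_config(max_iter = 100, g0 = 100, alpha = log(2))
  expect_equal(gravitational_constant(0, cfg), 100)
  expect_equal(gravitational_constant(100, cfg), 50)
  g <- vapply(0:100, gravitational_constant, numeric(1), config = cfg)
  expect_true(all(diff(g) < 0))
})

test_that("masses map fitness extremes to [0, 1] and normalize to one", {
  m <- update_masses(c(1, 3))
  expect_equal(m$m, c(1, 0))
  expect_equal(m$M, c(1, 0))
  expect_equal(update_masses(c(2, 2, 2))$M, rep(1 / 3, 3))
  for (s in 1:20) {
    set.seed(s)
    ms <- update_masses(runif(7))
    expect_equal(sum(ms$M), 1)
    expect_true(all(ms$m >= 0 & ms$m <= 1))
  }
})

test_that("forces vanish for coincident or massless agents", {
  cfg <- rgsa_config(n_agents = 2, max_iter = 10, variant = "classical")
  X <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  f <- compute_forces(X, c(0.7, 0.3), G = 10, kbest_idx = 1:2, cfg,
                      r = matrix(1, 2, 2))
  expect_equal(f, matrix(0, 2, 2))

  X2 <- rbind(c(0.1, 0.1), c(0.9, 0.9))
  f2 <- compute_forces(X2, c(0, 1), G = 10, kbest_idx = 1:2, cfg,
                       r = matrix(1, 2, 2))
  expect_equal(f2[2, ], c(0, 0))  # massless partner exerts nothing
})

test_that("expected classical force is half the deterministic refined force", {
  cfg_c <- rgsa_config(n_agents = 3, max_iter = 10, variant = "classical")
  cfg_r <- rgsa_config(n_agents = 3, max_iter = 10, variant = "refined", p = 1)
  set.seed(2)
  X <- matrix(runif(6), 3, 2)
  M <- c(0.5, 0.3, 0.2)
  full <- compute_forces(X, M, G = 5, kbest_idx = 1:3, cfg_r,
                         r = matrix(1, 3, 3))
  set.seed(10)
  draws <- replicate(4000, compute_forces(X, M, G = 5, kbest_idx = 1:3, cfg_c))
  expect_lt(max(abs(apply(draws, 1:2, mean) - full / 2)), 0.05 * max(abs(full)))
})

test_that("refined velocity coefficient reproduces both branch values", {
  expect_equal(rand_refined(1, rand_u = 0.5, rand_d = exp(-4)), 1)
  expect_equal(rand_refined(1, rand_u = 0.3, rand_g = 0), 0.4)
  set.seed(1)
  u <- runif(1e5)
  expect_equal(mean(log(1 / u) / 4), 0.25, tolerance = 0.01)
  draws <- rand_refined(1e4)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("motion update honors fixed points, substitution and clamping", {
  cfg <- rgsa_config(n_agents = 2, max_iter = 10)
  X <- rbind(c(0.2, 0.8), c(0.5, 0.5))
  Z <- matrix(0, 2, 2)
  still <- update_motion(X, Z, Z, c(0.5, 0.5), cfg, rand_i = c(0.3, 0.3))
  expect_equal(still$positions, X)

  mv <- update_motion(X, matrix(1, 2, 2), Z, c(0.5, 0.5), cfg,
                      rand_i = c(0.5, 0.5))
  expect_equal(mv$velocities, matrix(0.5, 2, 2))
  expect_equal(mv$positions[1, ], c(0.7, 1))  # clamped at the upper bound

  zero_mass <- update_motion(X, Z, matrix(5, 2, 2), c(0, 1), cfg,
                             rand_i = c(1, 1))
  expect_equal(zero_mass$positions[1, ], X[1, ])  # zero mass, zero acceleration
})

test_that("one classical iteration matches the brute-force pairwise oracle", {
  set.seed(42)
  X <- matrix(runif(6), 3, 2)
  V <- matrix(runif(6), 3, 2)
  fit <- c(2.5, 1.0, 4.0)
  r <- matrix(runif(9), 3, 3)
  rand_i <- runif(3)
  cfg <- rgsa_config(n_agents = 3, max_iter = 10, variant = "classical",
                     xi = 1e-6)
  G <- gravitational_constant(0, cfg)
  ms <- update_masses(fit)
  kb <- order(fit)[1:2]
  f_pkg <- compute_forces(X, ms$M, G, kb, cfg, r = r)
  mo_pkg <- update_motion(X, V, f_pkg, ms$M, cfg, rand_i = rand_i)
  oracle <- brute_gsa_iteration(X, V, fit, G, cfg$xi, kb, r, rand_i)
  expect_equal(ms$M, oracle$M)
  expect_equal(f_pkg, oracle$force, tolerance = 1e-12)
  expect_equal(mo_pkg$velocities, oracle$velocities, tolerance = 1e-12)
  expect_equal(mo_pkg$positions, oracle$positions, tolerance = 1e-12)
})

test_that("optimizer is elitist, deterministic, and stays in the unit cube", {
  sphere <- function(x) sum(x^2)
  cfg <- rgsa_config(n_agents = 10, max_iter = 40)
  r1 <- gsa_optimize(sphere, 5, cfg, seed = 3)
  r2 <- gsa_optimize(sphere, 5, cfg, seed = 3)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(diff(r1$history) <= 0))
  expect_true(all(r1$best_position >= 0 & r1$best_position <= 1))
  expect_equal(r1$best_fitness, min(r1$history))

  trap <- function(x) stop("boom")
  expect_error(gsa_optimize(trap, 2, rgsa_config(n_agents = 2, max_iter = 2)),
               "fitness evaluation failed")
})

test_that("geometric fitness is minimized at the centroid and matches a lattice scan", {
  mask <- array(FALSE, dim = c(8, 8, 8))
  mask[2:7, 2:7, 2:7] <- TRUE
  voi <- quantize(array(runif(512), dim = c(8, 8, 8)), mask, G = 4)
  co <- which(mask, arr.ind = TRUE)
  bb_lo <- apply(co, 2, min); bb_hi <- apply(co, 2, max)
  # exhaustive lattice scan inside the bounding box
  brute <- expand.grid(x = 2:7, y = 2:7, z = 2:7)
  brute$fit <- apply(brute, 1, function(pt) {
    sum((co[, 1] - pt[1])^2 + (co[, 2] - pt[2])^2 + (co[, 3] - pt[3])^2)
  })
  for (i in c(1, 50, 111, 216)) {
    u <- (unlist(brute[i, 1:3]) - bb_lo) / (bb_hi - bb_lo)
    expect_equal(geometric_fitness(u, voi), brute$fit[i])
  }
  cen_u <- (colMeans(co) - bb_lo) / (bb_hi - bb_lo)
  expect_lte(geometric_fitness(cen_u, voi), min(brute$fit))

  one <- array(FALSE, dim = c(8, 8, 8)); one[3, 4, 5] <- TRUE
  voi1 <- quantize(array(1, dim = c(8, 8, 8)), one, G = 2)
  expect_equal(geometric_fitness(c(0.5, 0.5, 0.5), voi1), 0)
})
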