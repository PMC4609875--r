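#' Configuration of the gravitational search optimizer
#'
#' @param n_agents Population size N (default 100).
#' @param max_iter Iteration cap T (default 500).
#' @param g0 Initial gravitational coefficient (default 100).
#' @param alpha Decay exponent of the gravitational coefficient (default 20,
#'   the standard setting).
#' @param xi Softening constant added to pairwise distances.
#' @param p Bernoulli force-existence probability of the refined variant,
#'   in (0, 1].
#' @param variant `"classical"` or `"refined"`.
#' @param seed Optional RNG seed used by [gsa_optimize()].
#' @return An object of class `rgsa_config`.
#' @export
rgsa_config <- function(n_agents = 100, max_iter = 500, g0 = 100, alpha = 20,
                        xi = 1e-6, p = 0.8,
                        variant = c("refined", "classical"), seed = NULL) {
  variant <- match.arg(variant)
  if (n_agents < 2) stop("`n_agents` must be >= 2", call. = FALSE)
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 max_iter = as.integer(max_iter), g0 = g0, alpha = alpha,
                 xi = xi, p = p, variant = variant, seed = seed),
            class = "rgsa_config")
}

#' Gravitational coefficient schedule
#'
#' `G(t) = G0 * exp(-alpha * t / T)`, strictly decreasing in `t` for positive
#' `alpha`.
#'
#' @param t Iteration, `0 <= t <= T`.
#' @param config An [rgsa_config()].
#' @return Scalar G(t).
#' @export
gravitational_constant <- function(t, config) {
  stopifnot(t >= 0, t <= config$max_iter)
  config$g0 * exp(-config$alpha * t / config$max_iter)
}

#' Fitness-derived agent masses
#'
#' For minimization, `best = min(fit)`, `worst = max(fit)`, raw mass
#' `m_i = (fit_i - worst) / (best - worst)` and normalized inertial mass
#' `M_i = m_i / sum(m)`. When all fitnesses are equal the masses are uniform
#' (`m_i = 1`, `M_i = 1/N`).
#'
#' @param fitnesses Numeric vector, one value per agent (length >= 2).
#' @return List with `m` (raw masses in `[0, 1]`) and `M` (normalized masses
#'   summing to 1).
#' @export
update_masses <- function(fitnesses) {
  stopifnot(length(fitnesses) >= 2, all(is.finite(fitnesses)))
  best <- min(fitnesses); worst <- max(fitnesses)
  if (best == worst) {
    n <- length(fitnesses)
    return(list(m = rep(1, n), M = rep(1 / n, n)))
  }
  m <- (fitnesses - worst) / (best - worst)
  list(m = m, M = m / sum(m))
}

#' Resultant gravitational forces on every agent
#'
#' Pairwise force of attractor j on agent i in dimension d:
#' `G * M_i * M_j / (R_ij + xi) * (x_j - x_i)` with `R_ij` the Euclidean
#' distance. Only the `K` best agents attract. Each pairwise contribution is
#' weighted by a random coefficient: uniform on `[0, 1]` in the classical
#' variant, Bernoulli(p) ("force exists or not") in the refined variant.
#'
#' @param positions N x n matrix of agent positions.
#' @param M Normalized masses, length N.
#' @param G Current gravitational coefficient.
#' @param kbest_idx Indices of the attracting agents.
#' @param config An [rgsa_config()] (supplies `xi`, `p`, `variant`).
#' @param r Optional N x N matrix of pairwise random weights (row = attracted
#'   agent, column = attractor); drawn internally when `NULL`. Exposed for
#'   deterministic verification.
#' @return N x n matrix of resultant forces.
#' @export
compute_forces <- function(positions, M, G, kbest_idx, config, r = NULL) {
  N <- nrow(positions)
  n <- ncol(positions)
  if (is.null(r)) {
    # one weight per attractor j, shared by every attracted agent
    rj <- if (config$variant == "refined") {
      rbinom(N, 1, config$p)
    } else {
      runif(N)
    }
    r <- matrix(rj, N, N, byrow = TRUE)
  }
  Fm <- matrix(0, N, n)
  for (j in kbest_idx) {
    if (M[j] == 0) next
    diffs <- sweep(positions, 2, positions[j, ], `-`) * -1  # x_j - x_i
    R <- sqrt(rowSums(diffs^2))
    w <- G * M * M[j] / (R + config$xi) * r[, j]
    w[j] <- 0
    Fm <- Fm + diffs * w
  }
  Fm
}

#' Velocity-memory coefficient of the refined variant
#'
#' With probability 0.6 (when a uniform draw exceeds 0.4) the coefficient is
#' `ln(1 / U) / 4` for a fresh uniform `U` (a logarithmic, heavy-tailed
#' exploration term with mean 1/4); otherwise it is `0.4 + 0.1 * Z` for a
#' standard normal `Z` (an exploitation term concentrated near 0.4). The
#' result is clamped to `[0, 1]` since it weights the retained velocity.
#'
#' @param n Number of draws.
#' @param rand_u,rand_d,rand_g Optional pre-drawn randoms (uniform, uniform,
#'   standard normal) for deterministic verification.
#' @param clamp Clamp to `[0, 1]` (default TRUE).
#' @return Numeric vector of length `n`.
#' @export
rand_refined <- function(n = 1, rand_u = NULL, rand_d = NULL, rand_g = NULL,
                         clamp = TRUE) {
  if (is.null(rand_u)) rand_u <- runif(n)
  if (is.null(rand_d)) rand_d <- runif(n)
  if (is.null(rand_g)) rand_g <- rnorm(n)
  out <- ifelse(rand_u > 0.4, log(1 / rand_d) / 4, 0.4 + 0.1 * rand_g)
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' One velocity/position update of the swarm
#'
#' Acceleration `a_i = F_i / M_i` (zero-mass agents get zero acceleration),
#' velocity `v' = rand_i * v + a` with a per-agent memory coefficient
#' (uniform for the classical variant, [rand_refined()] for the refined one),
#' position `x' = clamp(x + v', 0, 1)`.
#'
#' @param positions,velocities N x n matrices.
#' @param forces N x n force matrix from [compute_forces()].
#' @param M Normalized masses.
#' @param config An [rgsa_config()].
#' @param rand_i Optional per-agent memory coefficients (length N) for
#'   deterministic verification.
#' @return List with updated `positions` and `velocities`.
#' @export
update_motion <- function(positions, velocities, forces, M, config,
                          rand_i = NULL) {
  N <- nrow(positions)
  acc <- forces / ifelse(M > 0, M, Inf)  # zero mass -> zero acceleration
  if (is.null(rand_i)) {
    rand_i <- if (config$variant == "refined") rand_refined(N) else runif(N)
  }
  v <- velocities * rand_i + acc
  x <- pmin(pmax(positions + v, 0), 1)
  list(positions = x, velocities = v)
}

kbest_count <- function(t, config) {
  N <- config$n_agents
  max(1L, as.integer(round(N + (1 - N) * t / config$max_iter)))
}

#' Run the gravitational search optimizer
#'
#' Minimizes `fitness_fn` over the unit hypercube `[0, 1]^n_dim`. Agent
#' positions and velocities are initialized uniformly on `[0, 1]`; each
#' iteration evaluates all agents, updates masses,
#' applies forces from the current k-best set (shrinking linearly from N to 1)
#' and moves the swarm. Best-so-far bookkeeping is elitist: the returned
#' solution is the best position ever evaluated.
#'
#' @param fitness_fn Function mapping a position vector in `[0, 1]^n_dim` to a
#'   finite scalar (smaller is better).
#' @param n_dim Search-space dimension.
#' @param config An [rgsa_config()].
#' @param seed RNG seed (overrides `config$seed`).
#' @return An object of class `gsa_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far fitness per iteration, monotone non-increasing),
#'   `n_evaluations`, `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gsa_optimize(sphere, n_dim = 5,
#'                     rgsa_config(n_agents = 10, max_iter = 30), seed = 1)
#' res$best_fitness
#' @export
gsa_optimize <- function(fitness_fn, n_dim, config = rgsa_config(),
                         seed = config$seed) {
  stopifnot(inherits(config, "rgsa_config"), n_dim >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  N <- config$n_agents
  Tm <- config$max_iter
  X <- matrix(runif(N * n_dim), N, n_dim)
  V <- matrix(runif(N * n_dim), N, n_dim)
  best_fit <- Inf
  best_pos <- X[1, ]
  history <- numeric(Tm)
  n_eval <- 0L
  for (t in seq_len(Tm) - 1L) {
    fit <- apply(X, 1, function(x) {
      f <- tryCatch(fitness_fn(x), error = function(e) stop(sprintf(
        "fitness evaluation failed at iteration %d: %s", t,
        conditionMessage(e)), call. = FALSE))
      if (!is.finite(f)) stop("fitness_fn returned a non-finite value",
                              call. = FALSE)
      f
    })
    n_eval <- n_eval + N
    it_best <- which.min(fit)
    if (fit[it_best] < best_fit) {
      best_fit <- fit[it_best]
      best_pos <- X[it_best, ]
    }
    history[t + 1] <- best_fit
    G <- gravitational_constant(t, config)
    ms <- update_masses(fit)
    K <- kbest_count(t, config)
    kbest_idx <- order(fit)[seq_len(K)]
    Fo <- compute_forces(X, ms$M, G, kbest_idx, config)
    mo <- update_motion(X, V, Fo, ms$M, config)
    X <- mo$positions
    V <- mo$velocities
  }
  structure(list(best_position = best_pos, best_fitness = best_fit,
                 history = history, n_evaluations = n_eval, config = config),
            class = "gsa_result")
}

#' Sum of squared distances from a point to all region voxels
#'
#' A geometric benchmark fitness for the optimizer: a position in `[0, 1]^3`
#' is decoded to a point in the region's bounding box; the fitness is the sum
#' of squared Euclidean distances from that point to every in-mask voxel, so
#' the global minimum is the region centroid. Points whose nearest voxel is
#' not in the mask incur an additive penalty proportional to the squared
#' distance to the mask.
#'
#' @param position Numeric vector of length 3 in `[0, 1]^3`.
#' @param voi A [quantize()]d region.
#' @return Scalar fitness (smaller is better).
#' @export
geometric_fitness <- function(position, voi) {
  stopifnot(inherits(voi, "quantized_voi"), length(position) == 3)
  if (voi$n_voxels == 0) stop("empty VOI", call. = FALSE)
  co <- which(voi$mask, arr.ind = TRUE)
  bb_lo <- apply(co, 2, min); bb_hi <- apply(co, 2, max)
  P <- bb_lo + position * (bb_hi - bb_lo)
  d2 <- (co[, 1] - P[1])^2 + (co[, 2] - P[2])^2 + (co[, 3] - P[3])^2
  fit <- sum(d2)
  nearest <- round(P)
  inside <- all(nearest >= 1) && all(nearest <= dim(voi$mask)) &&
    voi$mask[nearest[1], nearest[2], nearest[3]]
  if (!inside) fit <- fit + voi$n_voxels * min(d2)
  fit
}
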