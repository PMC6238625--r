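#' Latin hypercube initialization of parameter vectors
#'
#' Draws `n` points such that for every parameter dimension exactly one
#' sample falls in each of the `n` equal-width bins of its bound interval.
#'
#' @param n Number of points.
#' @param bounds List with `lower` and `upper` numeric vectors.
#' @param seed RNG seed.
#' @return An `n` x `d` matrix; columns named as the bounds.
#' @export
latin_hypercube_init <- function(n, bounds, seed = 1) {
  stopifnot(n >= 1)
  lo <- bounds$lower; hi <- bounds$upper
  d <- length(lo)
  set.seed(seed)
  u <- lhs::randomLHS(n, d)
  x <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(x) <- names(lo)
  x
}

#' Swarm configuration for particle swarm optimization
#'
#' Defaults: inertia decreasing linearly from 0.9 to 0.4, cognitive and
#' social weights 1.494, ring neighborhood of 5 particles, velocities
#' clamped to 20% of each parameter range.
#'
#' @param n_particles,n_iterations Swarm size and iteration count.
#' @param inertia_start,inertia_end Linear inertia schedule.
#' @param cognitive,social Acceleration weights.
#' @param neighborhood Ring-neighborhood size (odd, <= n_particles).
#' @param v_clamp Velocity clamp as a fraction of each range.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 40, n_iterations = 500,
                         inertia_start = 0.9, inertia_end = 0.4,
                         cognitive = 1.494, social = 1.494,
                         neighborhood = 5, v_clamp = 0.2) {
  stopifnot(n_particles >= 2, inertia_end <= inertia_start,
            neighborhood <= n_particles)
  structure(list(n_particles = n_particles, n_iterations = n_iterations,
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 cognitive = cognitive, social = social,
                 neighborhood = neighborhood, v_clamp = v_clamp),
            class = "swarm_config")
}

#' Particle swarm optimization with ring neighborhood
#'
#' Standard inertia-weighted PSO: each particle's velocity is attracted to
#' its personal best and to the best position in its ring neighborhood;
#' positions are clipped to the bounds (with the velocity zeroed in clipped
#' dimensions); non-finite objective values are treated as `+Inf`.
#'
#' @param objective Function mapping a bounds-respecting vector to a scalar.
#' @param bounds List with `lower` and `upper`.
#' @param config A [swarm_config()].
#' @param seed RNG seed (controls initialization and velocity randomness).
#' @param seeded_particles Optional matrix of initial positions (rows) that
#'   replace the first rows of the Latin hypercube initialization.
#' @return List with `par` (best position), `value` (best objective),
#'   `trace` (global best per iteration, non-increasing), `n_evals`.
#' @export
run_pso <- function(objective, bounds, config = swarm_config(), seed = 1,
                    seeded_particles = NULL) {
  lo <- bounds$lower; hi <- bounds$upper
  d <- length(lo); n <- config$n_particles
  rng <- hi - lo
  X <- latin_hypercube_init(n, bounds, seed = seed)
  if (!is.null(seeded_particles)) {
    sp <- matrix(seeded_particles, ncol = d)
    k <- min(nrow(sp), n)
    X[seq_len(k), ] <- sp[seq_len(k), , drop = FALSE]
  }
  X <- sweep(sweep(X, 2, hi, pmin), 2, lo, pmax)
  vmax <- config$v_clamp * rng
  set.seed(seed + 1L)
  V <- matrix(stats::runif(n * d, -1, 1), n, d) *
    matrix(vmax, n, d, byrow = TRUE) * 0.1
  evalf <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  fX <- apply(X, 1, evalf)
  P <- X; fP <- fX
  half <- (config$neighborhood - 1) %/% 2
  neigh <- lapply(seq_len(n), function(i)
    unique(((i - 1 + seq(-half, half)) %% n) + 1L))
  trace <- numeric(config$n_iterations)
  gbest <- which.min(fP)
  for (it in seq_len(config$n_iterations)) {
    w <- config$inertia_start +
      (config$inertia_end - config$inertia_start) *
      (it - 1) / max(config$n_iterations - 1, 1)
    L <- do.call(rbind, lapply(seq_len(n), function(i) {
      j <- neigh[[i]][which.min(fP[neigh[[i]]])]
      P[j, , drop = FALSE]
    }))
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    V <- w * V + config$cognitive * r1 * (P - X) + config$social * r2 * (L - X)
    V <- pmin(pmax(V, matrix(-vmax, n, d, byrow = TRUE)),
              matrix(vmax, n, d, byrow = TRUE))
    X <- X + V
    lo_m <- matrix(lo, n, d, byrow = TRUE)
    hi_m <- matrix(hi, n, d, byrow = TRUE)
    clipped <- X < lo_m | X > hi_m
    X <- pmin(pmax(X, lo_m), hi_m)
    V[clipped] <- 0
    fX <- apply(X, 1, evalf)
    better <- fX < fP
    P[better, ] <- X[better, , drop = FALSE]
    fP[better] <- fX[better]
    gbest <- which.min(fP)
    trace[it] <- fP[gbest]
  }
  list(par = stats::setNames(P[gbest, ], names(lo)), value = fP[gbest],
       trace = cummin(trace), n_evals = n * (config$n_iterations + 1))
}

# Internal: build the VFO-seeded initial swarm.  One particle sits exactly
# at the VFO optimum; a fraction rho of the remaining swarm has its kinetic
# parameters (a, K, r, d) resampled uniformly within +/- 25% of the VFO
# values (clipped to bounds) while delays stay at their Latin hypercube
# draws.
vfo_seed_swarm <- function(lhs_init, vfo_params, bounds, rho = 0.25,
                           seed = 1) {
  X <- lhs_init
  n <- nrow(X)
  nm <- names(bounds$lower)
  X[1, ] <- as.numeric(vfo_params)
  n_emph <- floor(rho * n)
  if (n_emph > 0 && n > 1) {
    kin <- which(!startsWith(nm, "tau_"))
    rows <- 1 + seq_len(min(n_emph, n - 1))
    set.seed(seed + 2L)
    for (i in rows) {
      fac <- stats::runif(length(kin), 0.75, 1.25)
      v <- as.numeric(vfo_params)[kin] * fac
      X[i, kin] <- pmin(pmax(v, bounds$lower[kin]), bounds$upper[kin])
    }
  }
  X
}

#' Fit the clock model to an expression profile
#'
#' The full optimization pipeline for one profile: optional gradient-
#' matching initialization ([run_vfo()]) seeds the swarm (one particle at
#' the VFO optimum and a fraction `rho` of particles with kinetic
#' parameters pre-emphasized around it), then particle swarm optimization
#' minimizes the feature score of [evaluate_params()].
#'
#' @param profile A `clock_profile`.
#' @param topo A `clock_topology`.
#' @param config A [swarm_config()].
#' @param seed RNG seed; with `config` and `profile` it fully determines
#'   the result.
#' @param use_vfo Seed the swarm by gradient matching?
#' @param bounds Parameter bounds.
#' @param tol Scoring tolerances.
#' @param duration,step,transient Simulation controls for each objective
#'   evaluation.
#' @param vfo_starts Number of VFO random starts.
#' @param rho Fraction of the swarm pre-emphasized around the VFO optimum.
#' @param zoom_stages After the main swarm run, number of restart stages in
#'   which a smaller swarm searches a box contracted around the incumbent
#'   best (width `zoom_width^k` of each parameter range at stage `k`); the
#'   incumbent seeds each stage, so the best score never worsens.  The
#'   contraction mirrors how swarm velocities shrink as particles converge
#'   and is what makes desk-scale budgets reach the narrow low-score basins.
#' @param zoom_width Per-stage box contraction factor.
#' @param zoom_config Swarm configuration of the zoom stages.
#' @return A `clock_fit`: list with `params`, `score` (a `clock_score`),
#'   `trace`, `tissue`, `seed`, `vfo_used`, `config`, and the simulation
#'   controls used.
#' @export
fit_profile <- function(profile, topo = default_topology(),
                        config = swarm_config(), seed = 1, use_vfo = TRUE,
                        bounds = parameter_bounds(topo),
                        tol = clock_tolerances(), duration = 720,
                        step = 0.05, transient = 480, vfo_starts = 20,
                        rho = 0.25, zoom_stages = 3, zoom_width = 0.3,
                        zoom_config = swarm_config(n_particles = 20,
                                                   n_iterations = 80)) {
  data_features <- profile_features(profile)
  obj <- function(p) {
    evaluate_params(p, profile, topo, tol, duration = duration, step = step,
                    transient = transient, data_features = data_features)$total
  }
  seeded <- NULL
  vfo_res <- NULL
  if (use_vfo) {
    vfo_res <- run_vfo(profile, topo, bounds, n_starts = vfo_starts,
                       seed = seed)
    lhs0 <- latin_hypercube_init(config$n_particles, bounds, seed = seed)
    seeded <- vfo_seed_swarm(lhs0, vfo_res$params, bounds, rho = rho,
                             seed = seed)
  }
  res <- run_pso(obj, bounds, config, seed = seed,
                 seeded_particles = seeded)
  trace <- res$trace
  if (zoom_stages > 0) {
    rng <- bounds$upper - bounds$lower
    for (st in seq_len(zoom_stages)) {
      w <- zoom_width^st
      bz <- list(lower = pmax(bounds$lower, res$par - w * rng),
                 upper = pmin(bounds$upper, res$par + w * rng))
      rz <- run_pso(obj, bz, zoom_config, seed = seed + 1000L * st,
                    seeded_particles = matrix(res$par, nrow = 1))
      if (rz$value <= res$value) res <- rz
      trace <- c(trace, rz$trace)
    }
  }
  res$trace <- cummin(trace)
  best <- clock_params(res$par, topo)
  final <- evaluate_params(best, profile, topo, tol, duration = duration,
                           step = step, transient = transient,
                           data_features = data_features)
  structure(list(params = best, score = final, trace = res$trace,
                 tissue = profile$tissue, seed = as.integer(seed),
                 vfo_used = use_vfo,
                 vfo_residual = if (use_vfo) vfo_res$residual else NA_real_,
                 config = config, duration = duration, step = step,
                 transient = transient, tol = tol),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("Clock fit (%s): score %.4g, seed %d, VFO %s\n",
              x$tissue, x$score$total, x$seed,
              if (x$vfo_used) "on" else "off"))
  invisible(x)
}
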