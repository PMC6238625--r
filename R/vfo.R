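#' Fold a 48-h profile onto one 24-h cycle
#'
#' Averages the two sampled days pointwise (samples at `t` and `t + 24`)
#' and builds a periodic cubic interpolant per gene, the substrate for
#' derivative estimation in gradient-matching initialization.
#'
#' @param profile A `clock_profile` with 24 samples at 2-h spacing (0-46 h).
#' @return A `clock_cycle`: list with `times` (0, 2, ..., 22), `values`
#'   (gene x 12), and `interp` (list of periodic interpolating functions
#'   accepting any time in hours).
#' @export
fold_average_days <- function(profile) {
  stopifnot(inherits(profile, "clock_profile"))
  if (length(profile$times) != 24 ||
      !isTRUE(all.equal(profile$times, seq(0, 46, by = 2))))
    stop("day folding expects 24 samples at 0, 2, ..., 46 h")
  day1 <- profile$values[, 1:12, drop = FALSE]
  day2 <- profile$values[, 13:24, drop = FALSE]
  v <- (day1 + day2) / 2
  times <- seq(0, 22, by = 2)
  colnames(v) <- times
  interp <- lapply(profile$genes, function(g) {
    f <- stats::splinefun(c(times, 24), c(v[g, ], v[g, 1]),
                          method = "periodic")
    function(t, deriv = 0) f(t %% 24, deriv = deriv)
  })
  names(interp) <- profile$genes
  structure(list(times = times, values = v, interp = interp,
                 genes = profile$genes), class = "clock_cycle")
}

#' Periodic central-difference derivatives of a folded cycle
#'
#' Estimates `dx/dt` at the 12 grid points as
#' `(x(t + 2) - x(t - 2)) / 4` with periodic wraparound.
#'
#' @param cycle A `clock_cycle` from [fold_average_days()].
#' @return Gene x 12 matrix of derivatives (per hour).
#' @export
estimate_derivatives <- function(cycle) {
  stopifnot(inherits(cycle, "clock_cycle"))
  v <- cycle$values
  n <- ncol(v)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  d <- (v[, ip, drop = FALSE] - v[, im, drop = FALSE]) / 4
  colnames(d) <- cycle$times
  d
}

#' Gradient-matching objective (vector field optimization)
#'
#' Sum of squared differences, over genes and cycle grid points, between
#' the data-derived time derivatives and the model right-hand side
#' `production_rate - d_g x_g` evaluated along the folded cycle; delayed
#' regulator levels are read from the periodic interpolant, so the
#' objective is smooth in the delays and requires no integration.
#'
#' @param params Flat parameter vector.
#' @param cycle A `clock_cycle`.
#' @param derivs Matrix from [estimate_derivatives()].
#' @param topo A `clock_topology`.
#' @return Non-negative residual sum of squares.
#' @export
vfo_objective <- function(params, cycle, derivs, topo = default_topology()) {
  sp <- split_params(params, topo)
  e <- topo$edges
  genes <- topo$genes
  tgrid <- cycle$times
  # one delayed lookup per regulator (its delay is shared by all its edges)
  ydel <- lapply(seq_along(genes), function(si)
    pmax(cycle$interp[[si]](tgrid - sp$tau[si]), 0))
  prod <- matrix(1, length(genes), length(tgrid),
                 dimnames = list(genes, NULL))
  src_i <- match(e$source, genes)
  for (i in seq_len(nrow(e))) {
    y <- ydel[[src_i[i]]]
    f <- if (e$mode[i] == "activation")
      activation_factor(y, sp$a[i], sp$K[i], e$n[i])
    else
      inhibition_factor(y, sp$r[i], e$n[i])
    prod[e$target[i], ] <- prod[e$target[i], ] * f
  }
  rhs <- prod - sp$d * cycle$values[genes, , drop = FALSE]
  sum((derivs[genes, , drop = FALSE] - rhs)^2)
}

#' Analytic gradient of the gradient-matching objective
#'
#' Exact partial derivatives of [vfo_objective()] with respect to all
#' parameters (activation folds and thresholds, inhibition strengths,
#' degradation rates and delays; the delay derivatives use the periodic
#' interpolant's derivative).  Used by the bounded quasi-Newton
#' minimization in [run_vfo()].
#'
#' @inheritParams vfo_objective
#' @return Numeric gradient, same length and order as `params`.
#' @export
vfo_gradient <- function(params, cycle, derivs, topo = default_topology()) {
  sp <- split_params(params, topo)
  e <- topo$edges
  genes <- topo$genes
  G <- length(genes)
  tgrid <- cycle$times
  nt <- length(tgrid)
  src_i <- match(e$source, genes)
  tgt_i <- match(e$target, genes)
  ydel <- lapply(seq_len(G), function(si)
    pmax(cycle$interp[[si]](tgrid - sp$tau[si]), 0))
  ydot <- lapply(seq_len(G), function(si)
    cycle$interp[[si]](tgrid - sp$tau[si], deriv = 1))
  nE <- nrow(e)
  fmat <- matrix(0, nE, nt)     # factor per edge
  dfdy <- matrix(0, nE, nt)     # d factor / d delayed level
  dfda <- matrix(0, nE, nt); dfdK <- matrix(0, nE, nt)
  dfdr <- matrix(0, nE, nt)
  for (i in seq_len(nE)) {
    y <- ydel[[src_i[i]]]
    n <- e$n[i]
    if (e$mode[i] == "activation") {
      K <- sp$K[i]; a <- sp$a[i]
      q <- (y / K)^n
      fmat[i, ] <- (1 + a * q) / (1 + q)
      dfdq <- (a - 1) / (1 + q)^2
      dfda[i, ] <- q / (1 + q)
      dfdK[i, ] <- dfdq * (-n * q / K)
      dfdy[i, ] <- dfdq * (n / K) * (y / K)^(n - 1)
    } else {
      r <- sp$r[i]
      q <- (r * y)^n
      fmat[i, ] <- 1 / (1 + q)
      dfdq <- -1 / (1 + q)^2
      dfdr[i, ] <- dfdq * n * y * (r * y)^(n - 1)
      dfdy[i, ] <- dfdq * n * r * (r * y)^(n - 1)
    }
  }
  prod <- matrix(1, G, nt)
  for (i in seq_len(nE)) prod[tgt_i[i], ] <- prod[tgt_i[i], ] * fmat[i, ]
  X <- cycle$values[genes, , drop = FALSE]
  R <- derivs[genes, , drop = FALSE] - (prod - sp$d * X)
  # dF/d(edge factor f_i) = -2 R_target * prod/f_i
  coef <- matrix(0, nE, nt)
  for (i in seq_len(nE)) {
    pf <- prod[tgt_i[i], ] / fmat[i, ]
    coef[i, ] <- -2 * R[tgt_i[i], ] * pf
  }
  is_act <- e$mode == "activation"
  g_a <- rowSums(coef * dfda)[is_act]
  g_K <- rowSums(coef * dfdK)[is_act]
  g_r <- rowSums(coef * dfdr)[!is_act]
  g_d <- vapply(seq_len(G), function(g) sum(2 * R[g, ] * X[g, ]),
                numeric(1))
  # tau_s moves the delayed level of every edge with source s:
  # d ydel / d tau = -ydot
  g_tau <- vapply(seq_len(G), function(s) {
    idx <- which(src_i == s)
    if (!length(idx)) return(0)
    sum(vapply(idx, function(i)
      sum(coef[i, ] * dfdy[i, ] * (-ydot[[s]]) * (ydel[[s]] > 0)),
      numeric(1)))
  }, numeric(1))
  c(g_a, g_K, g_r, g_d, g_tau)
}

#' Gradient-matching parameter initialization (vector field optimization)
#'
#' Derives good starting parameters directly from the data's estimated time
#' derivatives: a bounded quasi-Newton minimization (`L-BFGS-B`) of
#' [vfo_objective()] is run from `n_starts` random bound-uniform starting
#' points, and the best result is returned.  No model integration is
#' performed.
#'
#' @param profile A `clock_profile`.
#' @param topo A `clock_topology`.
#' @param bounds Parameter bounds from [parameter_bounds()].
#' @param n_starts Number of random starts.
#' @param seed RNG seed.
#' @return List with `params` (a `clock_params`), `residual`, `converged`
#'   (any start converged), and `start_residuals`.
#' @export
run_vfo <- function(profile, topo = default_topology(),
                    bounds = parameter_bounds(topo), n_starts = 20,
                    seed = 1) {
  stopifnot(n_starts >= 1)
  cycle <- fold_average_days(profile)
  derivs <- estimate_derivatives(cycle)
  lo <- bounds$lower; hi <- bounds$upper
  d <- length(lo)
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * d, rep(lo, each = n_starts),
                                rep(hi, each = n_starts)), n_starts, d)
  best <- NULL; conv <- FALSE; start_res <- numeric(n_starts)
  for (k in seq_len(n_starts)) {
    p0 <- starts[k, ]
    start_res[k] <- vfo_objective(p0, cycle, derivs, topo)
    fit <- tryCatch(
      stats::optim(p0, vfo_objective, gr = vfo_gradient, cycle = cycle,
                   derivs = derivs, topo = topo, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("no VFO start converged; returning best raw start")
    k <- which.min(start_res)
    best <- list(par = starts[k, ], value = start_res[k])
  }
  par <- pmin(pmax(best$par, lo), hi)
  list(params = clock_params(par, topo), residual = best$value,
       converged = conv, start_residuals = start_res)
}
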