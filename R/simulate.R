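#' Simulate the delayed clock network
#'
#' Integrates the five delay-differential equations
#' `dx_g/dt = production_rate(g, delayed levels) - d_g x_g`
#' with a fixed-step explicit 4th-order scheme and cubic-Hermite
#' interpolation of the stored solution for the delayed lookups (method of
#' steps).  The pre-`t = 0` history is constant (default 1, the normalized
#' mean).  Genes and individual regulation terms can be clamped to
#' constants for the loop-dissection analysis.
#'
#' @param params A `clock_params` vector (see [clock_params()]).
#' @param topo A `clock_topology`.
#' @param history Constant history level, a single value or one per gene.
#' @param duration Simulated time span in hours.
#' @param step Integration step in hours (<= 0.1).
#' @param gene_clamp Named numeric vector: genes to freeze at a constant.
#' @param edge_clamp Numeric vector of length `nrow(topo$edges)` with `NA`
#'   for unclamped edges and the clamp constant otherwise.
#' @return A `clock_trajectory`: list with `times` (h), `values`
#'   (time x gene matrix), `derivs`, `step`, `genes`.
#' @export
simulate_clock <- function(params, topo = default_topology(), history = 1,
                           duration = 720, step = 0.05,
                           gene_clamp = NULL, edge_clamp = NULL) {
  validate_topology(topo)
  stopifnot(step <= 0.1, duration > 0)
  sp <- split_params(params, topo)
  if (duration <= max(sp$tau)) stop("duration must exceed the largest delay")
  G <- length(topo$genes)
  y0 <- rep_len(history, G)
  if (any(y0 < 0)) stop("history must be non-negative")
  gc <- rep(NA_real_, G)
  if (!is.null(gene_clamp)) {
    i <- match(names(gene_clamp), topo$genes)
    if (anyNA(i)) stop("unknown gene in gene_clamp")
    gc[i] <- as.numeric(gene_clamp)
  }
  ec <- if (is.null(edge_clamp)) rep(NA_real_, nrow(topo$edges)) else {
    stopifnot(length(edge_clamp) == nrow(topo$edges))
    as.numeric(edge_clamp)
  }
  cd <- topology_codes(topo)
  # simulation counter supports the guarantee that gradient-matching
  # initialization never integrates the model
  .clockloops_env$n_simulations <- .clockloops_env$n_simulations + 1L
  res <- dde_simulate_cpp(y0, duration, step, cd$target, cd$source, cd$type,
                          sp$a, sp$K, sp$r, cd$n, sp$d, sp$tau, gc, ec)
  values <- res$values
  colnames(values) <- topo$genes
  structure(list(times = res$times, values = values, derivs = res$derivs,
                 step = step, genes = topo$genes),
            class = "clock_trajectory")
}

.clockloops_env <- new.env(parent = emptyenv())
.clockloops_env$n_simulations <- 0L

#' Count of integrator calls made so far
#'
#' Used to assert that initialization procedures which must not simulate
#' (gradient matching) indeed perform zero integrations.
#' @param reset If `TRUE`, reset the counter to zero.
#' @return Integer count (before any reset).
#' @export
simulation_count <- function(reset = FALSE) {
  n <- .clockloops_env$n_simulations
  if (reset) .clockloops_env$n_simulations <- 0L
  n
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("Clock trajectory:", length(x$times), "points over",
      max(x$times), "h, step", x$step, "h\n")
  invisible(x)
}

# Internal: quadratically refined local maxima of a sampled signal.
# Returns times and values of all strict local maxima after `from`.
local_peaks <- function(times, x, from = 0) {
  n <- length(x)
  if (n < 3) return(list(t = numeric(0), v = numeric(0)))
  i <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  i <- i[times[i] >= from]
  if (!length(i)) return(list(t = numeric(0), v = numeric(0)))
  h <- times[2] - times[1]
  den <- x[i - 1] - 2 * x[i] + x[i + 1]
  off <- ifelse(abs(den) > 1e-12, 0.5 * (x[i - 1] - x[i + 1]) / den, 0)
  pv <- x[i] - 0.25 * (x[i - 1] - x[i + 1]) * off
  list(t = times[i] + off * h, v = pv)
}

#' Extract limit-cycle features from a trajectory
#'
#' Discards an initial transient, locates per-gene peaks by local-maximum
#' detection with quadratic interpolation, and reports the clock features
#' used for scoring: the free-running period `T` (mean peak-to-peak interval
#' of the reference gene), per-gene peak phases relative to the reference
#' gene's peak (in `[0, T)`), and per-gene fold changes (max/min over the
#' last full cycle).
#'
#' @param traj A `clock_trajectory`.
#' @param reference Reference gene for period and relative phases.
#' @param transient Hours to discard before analysis.
#' @return A `clock_features` list with `period`, `phase` (named, h),
#'   `fold_change` (named), `rhythmic` flag, and `reference`; if fewer than
#'   two reference peaks remain, `rhythmic` is `FALSE` and features are `NA`.
#' @export
extract_features <- function(traj, reference = "Bmal1", transient = 480) {
  stopifnot(inherits(traj, "clock_trajectory"))
  genes <- traj$genes
  t <- traj$times
  keep <- t >= transient
  nonrhythmic <- structure(
    list(period = NA_real_,
         phase = stats::setNames(rep(NA_real_, length(genes)), genes),
         fold_change = stats::setNames(rep(NA_real_, length(genes)), genes),
         rhythmic = FALSE, reference = reference),
    class = "clock_features")
  if (sum(keep) < 10) return(nonrhythmic)
  tt <- t[keep]
  X <- traj$values[keep, , drop = FALSE]
  ref <- X[, reference]
  # guard against flat signals where float ripple fakes peaks
  if (diff(range(ref)) < 1e-9 * max(mean(ref), 1e-12)) return(nonrhythmic)
  pk <- local_peaks(tt, ref)
  if (length(pk$t) < 2) return(nonrhythmic)
  period <- mean(diff(pk$t))
  if (!is.finite(period) || period <= 0) return(nonrhythmic)
  ref_peak <- pk$t[length(pk$t)]
  phase <- fold <- stats::setNames(rep(NA_real_, length(genes)), genes)
  cyc <- tt >= ref_peak - period & tt <= ref_peak
  for (g in genes) {
    pg <- local_peaks(tt, X[, g])
    if (length(pg$t)) {
      phase[g] <- (pg$t[length(pg$t)] - ref_peak) %% period
    } else phase[g] <- 0  # flat gene: phase undefined, conventionally 0
    xs <- X[cyc, g]
    fold[g] <- if (min(xs) > 0) max(xs) / min(xs) else Inf
  }
  phase[reference] <- 0
  structure(list(period = period, phase = phase, fold_change = fold,
                 rhythmic = TRUE, reference = reference),
            class = "clock_features")
}

#' @export
print.clock_features <- function(x, ...) {
  if (!x$rhythmic) { cat("Clock features: non-rhythmic\n"); return(invisible(x)) }
  cat(sprintf("Clock features: period %.2f h (reference %s)\n",
              x$period, x$reference))
  print(round(rbind(phase_h = x$phase, fold_change = x$fold_change), 3))
  invisible(x)
}

#' Sustained-rhythmicity test for a trajectory
#'
#' A trajectory counts as rhythmic when, after the transient, some gene
#' (or a specified gene) shows a relative amplitude `(max - min)/mean`
#' above `epsilon` and the amplitude of the last observed cycle is at least
#' `decay_min` times that of the previous cycle (sustained rather than
#' damped oscillation).
#'
#' @param traj A `clock_trajectory`.
#' @param transient Hours to discard.
#' @param epsilon Minimal relative amplitude.
#' @param decay_min Minimal ratio of successive cycle amplitudes.
#' @param gene Gene whose rhythm is probed, or `"any"` (default) to accept
#'   a sustained rhythm in any gene — appropriate under clamping, where
#'   genes downstream of a clamp are flat while the oscillator may live
#'   elsewhere.
#' @return Logical.
#' @export
is_rhythmic <- function(traj, transient = 480, epsilon = 0.01,
                        decay_min = 0.95, gene = "any") {
  stopifnot(inherits(traj, "clock_trajectory"))
  genes_to_check <- if (identical(gene, "any")) traj$genes else gene
  keep <- traj$times >= transient
  tt <- traj$times[keep]
  for (g in genes_to_check) {
    x <- traj$values[keep, g]
    m <- mean(x)
    if (m <= 0) next
    if ((max(x) - min(x)) / m <= epsilon) next
    pk <- local_peaks(tt, x)
    if (length(pk$t) < 3) next
    # amplitude of a cycle: peak minus the minimum down to the next peak
    np <- length(pk$t)
    amp_of_cycle <- function(t1, t2, pv) {
      pv - min(x[tt >= t1 & tt <= t2])
    }
    a_prev <- amp_of_cycle(pk$t[np - 2], pk$t[np - 1], pk$v[np - 2])
    a_last <- amp_of_cycle(pk$t[np - 1], pk$t[np], pk$v[np - 1])
    if (a_prev <= 0) next
    if (a_last / a_prev >= decay_min &&
        (pk$v[np - 1] - min(x)) / m > epsilon) return(TRUE)
  }
  FALSE
}

# Internal: time series of one edge's fold factor along a trajectory
# (delayed source level read from the stored trajectory; before-zero times
# use the first stored value, adequate once a transient is discarded).
edge_factor_series <- function(traj, e_idx, params, topo) {
  sp <- split_params(params, topo)
  ed <- topo$edges[e_idx, ]
  s <- ed$source
  tq <- traj$times - sp$tau[match(s, topo$genes)]
  y <- stats::approx(traj$times, traj$values[, s], xout = tq,
                     rule = 2)$y
  if (ed$mode == "activation")
    activation_factor(pmax(y, 0), sp$a[e_idx], sp$K[e_idx], ed$n)
  else
    inhibition_factor(pmax(y, 0), sp$r[e_idx], ed$n)
}
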