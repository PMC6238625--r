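#' Mean-normalize a gene-by-time expression table
#'
#' Divides each gene's time course by its temporal mean so expression is
#' dimensionless around 1, matching how circadian microarray profiles are
#' presented.
#'
#' @param values Numeric gene x time matrix (rownames = genes) or a
#'   `clock_profile`.
#' @param times Sampling times in hours (defaults to column names).
#' @param tissue Optional tissue label.
#' @return A `clock_profile`: list with `genes`, `times`, `values`
#'   (gene x time, mean 1 per gene), `tissue`.
#' @export
normalize_profile <- function(values, times = NULL, tissue = "unknown") {
  if (inherits(values, "clock_profile")) {
    times <- values$times; tissue <- values$tissue; values <- values$values
  }
  values <- as.matrix(values)
  if (is.null(times)) times <- as.numeric(colnames(values))
  stopifnot(length(times) == ncol(values), !anyNA(times))
  m <- rowMeans(values)
  if (any(m <= 0)) stop("non-positive gene mean; cannot mean-normalize")
  out <- sweep(values, 1, m, "/")
  colnames(out) <- times
  structure(list(genes = rownames(out), times = times, values = out,
                 tissue = tissue), class = "clock_profile")
}

#' @export
print.clock_profile <- function(x, ...) {
  cat("Clock expression profile (", x$tissue, "): ",
      length(x$genes), " genes x ", length(x$times), " samples, ",
      x$times[1], "-", x$times[length(x$times)], " h\n", sep = "")
  invisible(x)
}

# Internal: harmonic (fundamental + second harmonic, 24-h period) least
# squares fit of one mean-normalized time course.  Returns the fitted-curve
# evaluator plus peak time and fold change over [0, 24).
harmonic_fit <- function(times, x) {
  w <- 2 * pi / 24
  M <- cbind(1, cos(w * times), sin(w * times),
             cos(2 * w * times), sin(2 * w * times))
  b <- tryCatch(qr.solve(M, x), error = function(e)
    stop("singular harmonic fit"))
  f <- function(t) b[1] + b[2] * cos(w * t) + b[3] * sin(w * t) +
    b[4] * cos(2 * w * t) + b[5] * sin(2 * w * t)
  tg <- seq(0, 24, by = 0.01)[-2401]
  yg <- f(tg)
  list(coef = b, fun = f, peak = tg[which.max(yg)],
       fc = if (min(yg) > 0) max(yg) / min(yg) else Inf,
       amp1 = sqrt(b[2]^2 + b[3]^2) / b[1])
}

#' Clock features of a measured expression profile
#'
#' Fits each gene's time course with a 24-h fundamental plus second
#' harmonic by least squares (the data are entrained, so the data period is
#' fixed at 24 h), then reads peak phases relative to the reference gene's
#' fitted peak and fold changes (max/min of the fitted curve over one
#' cycle).
#'
#' @param profile A `clock_profile`.
#' @param reference Reference gene.
#' @return A `clock_features` object with `period = 24`.
#' @export
profile_features <- function(profile, reference = "Bmal1") {
  stopifnot(inherits(profile, "clock_profile"))
  if (length(profile$times) < 12 || diff(range(profile$times)) < 24)
    stop("need at least 12 samples spanning 24 h")
  genes <- profile$genes
  fits <- lapply(genes, function(g)
    harmonic_fit(profile$times, profile$values[g, ]))
  names(fits) <- genes
  ref_peak <- fits[[reference]]$peak
  phase <- vapply(fits, function(f) (f$peak - ref_peak) %% 24, numeric(1))
  fold <- vapply(fits, function(f) f$fc, numeric(1))
  phase[reference] <- 0
  structure(list(period = 24, phase = phase, fold_change = fold,
                 rhythmic = TRUE, reference = reference),
            class = "clock_features")
}

#' Scoring tolerances
#'
#' Deviations are scaled by tolerances chosen to represent experimental
#' day-to-day uncertainty: period 0.5 h, phase 1 h, fold change 0.5 log2
#' units.  Ten scored terms each at one tolerance give a score of 10, the
#' goodness threshold.
#'
#' @param sigma_period Period tolerance (h).
#' @param sigma_phase Phase tolerance (h).
#' @param sigma_fc Fold-change tolerance (log2 units).
#' @param penalty_nonrhythmic Score assigned to non-rhythmic simulations.
#' @return List of tolerances.
#' @export
clock_tolerances <- function(sigma_period = 0.5, sigma_phase = 1,
                             sigma_fc = 0.5, penalty_nonrhythmic = 1000) {
  stopifnot(sigma_period > 0, sigma_phase > 0, sigma_fc > 0,
            penalty_nonrhythmic > 0)
  list(sigma_period = sigma_period, sigma_phase = sigma_phase,
       sigma_fc = sigma_fc, penalty_nonrhythmic = penalty_nonrhythmic)
}

# circular distance along the shorter arc, on a cycle of length `period`
circular_distance <- function(x, y, period) {
  d <- (x - y) %% period
  pmin(d, period - d)
}

#' Score agreement between simulated and measured clock features
#'
#' Sum of squared tolerance-scaled deviations over 10 terms: one period
#' term, four relative-phase terms (all genes except the reference, circular
#' distance on the data period) and five log2 fold-change terms.
#'
#' @param sim,data `clock_features` for simulation and data.
#' @param tol Tolerances from [clock_tolerances()].
#' @return A `clock_score`: list with `total` and a `breakdown` vector.
#' @export
score_features <- function(sim, data, tol = clock_tolerances()) {
  stopifnot(identical(sort(names(sim$phase)), sort(names(data$phase))),
            identical(sim$reference, data$reference))
  if (!isTRUE(sim$rhythmic))
    return(structure(list(total = tol$penalty_nonrhythmic,
                          breakdown = c(penalty = tol$penalty_nonrhythmic),
                          nonrhythmic = TRUE), class = "clock_score"))
  genes <- names(data$phase)
  others <- setdiff(genes, data$reference)
  terms <- c(period = ((sim$period - data$period) / tol$sigma_period)^2)
  ph <- vapply(others, function(g)
    (circular_distance(sim$phase[g], data$phase[g], data$period) /
       tol$sigma_phase)^2, numeric(1))
  names(ph) <- paste0("phase_", others)
  fc <- vapply(genes, function(g)
    ((log2(sim$fold_change[g]) - log2(data$fold_change[g])) /
       tol$sigma_fc)^2, numeric(1))
  names(fc) <- paste0("fc_", genes)
  breakdown <- c(terms, ph, fc)
  structure(list(total = sum(breakdown), breakdown = breakdown,
                 nonrhythmic = FALSE), class = "clock_score")
}

#' @export
print.clock_score <- function(x, ...) {
  cat(sprintf("Clock score: %.4g\n", x$total))
  invisible(x)
}

#' Evaluate a parameter set against an expression profile
#'
#' Simulates the model, extracts limit-cycle features and scores them
#' against the profile's features.  Non-rhythmic or failed simulations
#' receive the flat non-rhythmic penalty.
#'
#' @param params A `clock_params` vector.
#' @param profile A `clock_profile` (or precomputed `clock_features` via
#'   `data_features`).
#' @param topo A `clock_topology`.
#' @param tol Tolerances.
#' @param duration,step,transient Simulation controls (hours).
#' @param data_features Optional precomputed [profile_features()] result,
#'   to avoid refitting the data in repeated evaluations.
#' @param reference Reference gene.
#' @return A `clock_score`.
#' @export
evaluate_params <- function(params, profile, topo = default_topology(),
                            tol = clock_tolerances(), duration = 720,
                            step = 0.05, transient = 480,
                            data_features = NULL, reference = "Bmal1") {
  if (is.null(data_features)) data_features <- profile_features(profile, reference)
  traj <- tryCatch(
    simulate_clock(params, topo, duration = duration, step = step),
    error = function(e) NULL)
  if (is.null(traj))
    return(structure(list(total = tol$penalty_nonrhythmic,
                          breakdown = c(penalty = tol$penalty_nonrhythmic),
                          nonrhythmic = TRUE, failed = TRUE),
                     class = "clock_score"))
  sim <- extract_features(traj, reference = reference, transient = transient)
  score_features(sim, data_features, tol)
}

#' Is a fit good (score below threshold)?
#'
#' A fit is kept for loop analysis when its score is strictly below the
#' threshold (default 10, i.e. root-mean-square deviation below one
#' tolerance unit across the ten scored terms).
#'
#' @param score A `clock_score` or a number.
#' @param threshold Goodness threshold.
#' @return Logical.
#' @export
is_good_fit <- function(score, threshold = 10) {
  s <- if (inherits(score, "clock_score")) score$total else as.numeric(score)
  s < threshold
}
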