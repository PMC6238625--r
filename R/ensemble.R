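#' Bundle fits and loop reports into an ensemble
#'
#' @param fits List of `clock_fit` objects.
#' @param reports List of `clock_loop_report` objects aligned with `fits`.
#' @return A `clock_ensemble`.
#' @export
clock_ensemble <- function(fits, reports) {
  stopifnot(length(fits) == length(reports))
  structure(list(fits = fits, reports = reports,
                 tissues = vapply(fits, function(f) f$tissue, character(1)),
                 scores = vapply(fits, function(f) f$score$total,
                                 numeric(1))),
            class = "clock_ensemble")
}

#' Loop-frequency table across tissues
#'
#' For each tissue, the fraction of good fits (score below `threshold`) in
#' which each core loop family is essential.
#'
#' @param ensemble A `clock_ensemble`.
#' @param threshold Goodness threshold on the fit score.
#' @param families Family names (default the four core families).
#' @return Family x tissue matrix of frequencies in `[0, 1]`.
#' @export
loop_frequency_table <- function(ensemble, threshold = 10,
                                 families = c("Per2_loop", "Cry1_loop",
                                              "Bmal1_RevErbA",
                                              "Repressilator")) {
  keep <- ensemble$scores < threshold
  tissues <- unique(ensemble$tissues)
  out <- matrix(0, length(families), length(tissues),
                dimnames = list(families, tissues))
  for (ts in tissues) {
    idx <- which(keep & ensemble$tissues == ts)
    if (!length(idx)) { out[, ts] <- NA_real_; next }
    for (fam in families)
      out[fam, ts] <- mean(vapply(ensemble$reports[idx], function(r)
        fam %in% r$essential_families, logical(1)))
  }
  out
}

#' Venn-style counts of oscillator composition
#'
#' Counts, for one tissue, how many fits have each possible union of core
#' families across their minimal rhythm-generating oscillators.  Counts
#' partition the fit set.
#'
#' @param ensemble A `clock_ensemble`.
#' @param tissue Tissue label (default: all fits).
#' @return Named integer vector; names are `+`-joined sorted family subsets
#'   (`"(none)"` for fits without oscillators).
#' @export
oscillator_venn <- function(ensemble, tissue = NULL) {
  idx <- if (is.null(tissue)) seq_along(ensemble$fits)
         else which(ensemble$tissues == tissue)
  keys <- vapply(ensemble$reports[idx], function(r) {
    fams <- sort(unique(unlist(r$minimal_oscillators)))
    if (!length(fams)) "(none)" else paste(fams, collapse = "+")
  }, character(1))
  table_to_named(table(keys))
}

table_to_named <- function(tb) stats::setNames(as.integer(tb), names(tb))

# Internal: fits-by-parameters matrix, standardized per column.
ensemble_param_matrix <- function(ensemble, standardize = TRUE) {
  X <- t(vapply(ensemble$fits, function(f) as.numeric(f$params),
                numeric(length(ensemble$fits[[1]]$params))))
  colnames(X) <- names(ensemble$fits[[1]]$params)
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- scale(X, center = TRUE, scale = s)
  }
  X
}

#' Principal-component projection of the parameter ensemble
#'
#' Standardizes the 34 kinetic parameters across fits and projects onto
#' the top two principal components; the loadings are the parameter-axis
#' arrows of the projection plane.
#'
#' @param ensemble A `clock_ensemble` with at least 3 fits.
#' @return A `clock_projection`: list with `coordinates` (fits x 2),
#'   `loadings` (parameters x 2), `explained` (variance fractions),
#'   `kind = "PCA"`.
#' @export
pca_project <- function(ensemble) {
  stopifnot(length(ensemble$fits) >= 3)
  X <- ensemble_param_matrix(ensemble)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  structure(list(coordinates = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 kind = "PCA"),
            class = "clock_projection")
}

#' Linear-discriminant projection separating tissues
#'
#' Projects standardized parameters onto the top two discriminants of the
#' between-tissue versus within-tissue scatter (ridge-regularized within
#' scatter, since 34 dimensions can exceed per-tissue fit counts).
#' Loadings are sorted by magnitude with the four largest flagged.
#'
#' @param ensemble A `clock_ensemble` with >= 2 tissues, each >= 2 fits.
#' @param ridge Ridge constant added to the within-class scatter diagonal.
#' @return A `clock_projection` with `kind = "LDA"`, plus `discriminant_ratios`
#'   and `top4` (names of the four largest-loading parameters on axis 1).
#' @export
lda_project <- function(ensemble, ridge = 1e-6) {
  tissues <- ensemble$tissues
  tab <- table(tissues)
  if (length(tab) < 2 || any(tab < 2))
    stop("LDA needs >= 2 tissues with >= 2 fits each")
  X <- ensemble_param_matrix(ensemble)
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (ts in names(tab)) {
    Xi <- X[tissues == ts, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  Sw <- Sw + ridge * diag(d)
  eg <- eigen(solve(Sw, Sb))
  k <- min(2, length(tab) - 1, d)
  W <- Re(eg$vectors[, seq_len(k), drop = FALSE])
  W <- apply(W, 2, function(w) w / sqrt(sum(w^2)))
  rownames(W) <- colnames(X)
  coords <- X %*% W
  mag <- sqrt(rowSums(W^2))
  structure(list(coordinates = coords, loadings = W,
                 discriminant_ratios = Re(eg$values[seq_len(k)]),
                 top4 = names(sort(mag, decreasing = TRUE))[1:4],
                 kind = "LDA"),
            class = "clock_projection")
}

#' Wilcoxon rank-sum test (exact for small samples, tie-corrected)
#'
#' Mann-Whitney rank-sum comparison of two samples: exact p-value by full
#' enumeration of group assignments when `min(n) <= 8`, normal
#' approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method`.
#' @export
ranksum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (min(n1, n2) <= 8 && choose(n1 + n2, n1) <= 5e5) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx)
      sum(rk[idx]) - n1 * (n1 + 1) / 2)
    p_le <- mean(Us <= U); p_ge <- mean(Us >= U)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z), greater = stats::pnorm(-z))
    method <- "normal"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Circular mean of phases
#'
#' Angle of the mean resultant vector on a cycle of length `period`,
#' mapped to `[0, period)`.  When the resultant length is (numerically)
#' zero the mean is undefined and `NA` is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param phases Phases in hours.
#' @param period Cycle length in hours.
#' @return Phase in `[0, period)`, or `NA` for a zero resultant.
#' @export
circular_mean <- function(phases, period = 24) {
  stopifnot(period > 0)
  ang <- 2 * pi * phases / period
  C <- mean(cos(ang)); S <- mean(sin(ang))
  if (sqrt(C^2 + S^2) < 1e-9)
    return(structure(NA_real_, degenerate = TRUE))
  out <- (atan2(S, C) * period / (2 * pi)) %% period
  if (period - out < 1e-9) out <- 0
  out
}

#' Invert repressor phases by half a cycle
#'
#' Shifts repressor peak phases by +12 h (mod 24) so their maximal
#' *activity* aligns with activator phases for direct comparison;
#' activator phases are unchanged.
#'
#' @param phases Named phases in hours on a 24-h cycle.
#' @param roles Character vector (`"activator"`/`"repressor"`) aligned
#'   with `phases`.
#' @return Phases with repressors shifted.
#' @export
invert_repressor_phases <- function(phases, roles) {
  stopifnot(length(phases) == length(roles),
            all(roles %in% c("activator", "repressor")))
  out <- phases
  rep_i <- roles == "repressor"
  out[rep_i] <- (phases[rep_i] + 12) %% 24
  out
}

#' Association between score and essential-loop count
#'
#' Splits the ensemble at the median score (fits exactly at the median go
#' to the lower half) and compares the number of essential core loops
#' between halves with the rank-sum test; also reports mean scores of fits
#' with versus without a given family.
#'
#' @param ensemble A `clock_ensemble` with >= 4 fits.
#' @param family Family whose with/without mean scores are reported.
#' @param alternative Passed to [ranksum()] comparing low-half counts vs
#'   high-half counts.
#' @return List with `median_score`, `n_low`, `n_high`,
#'   `mean_loops_low`, `mean_loops_high`, `ranksum`, `mean_score_with`,
#'   `mean_score_without`.
#' @export
score_loop_association <- function(ensemble, family = "Repressilator",
                                   alternative = "two.sided") {
  stopifnot(length(ensemble$fits) >= 4)
  scores <- ensemble$scores
  counts <- vapply(ensemble$reports, function(r)
    length(r$essential_families), numeric(1))
  med <- stats::median(scores)
  low <- scores <= med
  rs <- if (any(low) && any(!low))
    ranksum(counts[!low], counts[low], alternative = alternative)
  else  # all scores at the median: no split, no association
    list(statistic = NA_real_, p_value = 1, method = "degenerate")
  has_fam <- vapply(ensemble$reports, function(r)
    family %in% r$essential_families, logical(1))
  list(median_score = med, n_low = sum(low), n_high = sum(!low),
       mean_loops_low = mean(counts[low]),
       mean_loops_high = mean(counts[!low]),
       ranksum = rs,
       mean_score_with = if (any(has_fam)) mean(scores[has_fam]) else NA_real_,
       mean_score_without = if (any(!has_fam)) mean(scores[!has_fam])
                            else NA_real_)
}
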