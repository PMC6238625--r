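#' Activation fold factor
#'
#' Hill-type activation used for E-box and D-box regulation,
#' `(1 + a (y/K)^n) / (1 + (y/K)^n)`: the factor rises from 1 (no
#' regulator) and saturates at the maximum activation fold `a`; at the
#' threshold `y = K` it equals `(1 + a)/2`.
#'
#' @param y Delayed regulator level (mean-normalized units, >= 0).
#' @param a Maximum activation fold (>= 1).
#' @param K Activation threshold (> 0, mean-normalized units).
#' @param n Hill exponent (number of binding sites, >= 1).
#' @return Dimensionless fold in `[1, a]`.
#' @export
activation_factor <- function(y, a, K, n) {
  if (any(y < 0)) stop("regulator level must be non-negative")
  if (any(K <= 0)) stop("threshold K must be positive")
  q <- (y / K)^n
  (1 + a * q) / (1 + q)
}

#' Inhibition fold factor
#'
#' Single-parameter repression `1 / (1 + (r y)^n)`: 1 with no repressor,
#' 0.5 at `y = 1/r`, approaching 0 at saturation.
#'
#' @param y Delayed regulator level (>= 0).
#' @param r Inhibition strength (inverse mean-normalized units, > 0).
#' @param n Hill exponent (>= 1).
#' @return Dimensionless fold in `(0, 1]`.
#' @export
inhibition_factor <- function(y, r, n) {
  if (any(y < 0)) stop("regulator level must be non-negative")
  1 / (1 + (r * y)^n)
}

# Internal: fold factor of a single edge (row index into topo$edges).
edge_factor <- function(e_idx, y, params, topo) {
  sp <- split_params(params, topo)
  ed <- topo$edges[e_idx, ]
  if (ed$mode == "activation")
    activation_factor(y, sp$a[e_idx], sp$K[e_idx], ed$n)
  else
    inhibition_factor(y, sp$r[e_idx], ed$n)
}

#' Transcription production rate of one gene
#'
#' The production rate of a gene is the product of the activation and
#' inhibition fold factors over all its incoming regulations, evaluated at
#' the delayed regulator levels (an empty product is 1).
#'
#' @param gene Gene name.
#' @param delayed_levels Named numeric vector giving `x_s(t - tau_s)` for
#'   every regulator `s` of `gene`.
#' @param params A `clock_params` vector.
#' @param topo A `clock_topology`.
#' @return Production rate in mean-normalized units per hour.
#' @export
production_rate <- function(gene, delayed_levels, params, topo = default_topology()) {
  idx <- which(topo$edges$target == gene)
  prod <- 1
  for (i in idx) {
    s <- topo$edges$source[i]
    if (!s %in% names(delayed_levels))
      stop("missing delayed level for regulator ", s)
    prod <- prod * edge_factor(i, delayed_levels[[s]], params, topo)
  }
  prod
}
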