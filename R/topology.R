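#' Gene names of the five-gene core clock network
#'
#' The reduced mammalian core-clock network uses five representative genes:
#' the activators Bmal1 and Dbp and the inhibitors Per2, Cry1 and RevErbA
#' (Rev-erb-alpha).  Order is fixed and defines the index of each gene in
#' trajectories and parameter vectors.
#'
#' @return Character vector of length 5.
#' @export
clock_genes <- function() {
  c("Bmal1", "Dbp", "Per2", "Cry1", "RevErbA")
}

#' Default 17-edge regulation topology of the core clock
#'
#' Builds the signed, element-annotated regulation graph over the five genes:
#' Bmal1 activates Dbp, Per2, Cry1 and RevErbA through E-boxes; Dbp activates
#' Per2, Cry1 and RevErbA through D-boxes; Per2 and Cry1 each inhibit Dbp,
#' Per2, Cry1 and RevErbA through E-boxes; RevErbA inhibits Bmal1 and Cry1
#' through RREs.  That yields 7 activations and 10 inhibitions.  Each edge
#' carries a Hill-type exponent interpreted as the number of binding sites
#' (default 3 for every edge, overridable).
#'
#' @param exponents Either a single integer used for every edge or a numeric
#'   vector of length 17 in edge order (activations first).
#' @return An object of class `clock_topology`: a list with `genes` and an
#'   `edges` data frame (columns `source`, `target`, `mode`, `element`, `n`).
#' @export
default_topology <- function(exponents = 3L) {
  genes <- clock_genes()
  act <- rbind(
    c("Bmal1", "Dbp",     "Ebox"),
    c("Bmal1", "Per2",    "Ebox"),
    c("Bmal1", "Cry1",    "Ebox"),
    c("Bmal1", "RevErbA", "Ebox"),
    c("Dbp",   "Per2",    "Dbox"),
    c("Dbp",   "Cry1",    "Dbox"),
    c("Dbp",   "RevErbA", "Dbox"))
  inh <- rbind(
    c("Per2",    "Dbp",     "Ebox"),
    c("Per2",    "Per2",    "Ebox"),
    c("Per2",    "Cry1",    "Ebox"),
    c("Per2",    "RevErbA", "Ebox"),
    c("Cry1",    "Dbp",     "Ebox"),
    c("Cry1",    "Per2",    "Ebox"),
    c("Cry1",    "Cry1",    "Ebox"),
    c("Cry1",    "RevErbA", "Ebox"),
    c("RevErbA", "Bmal1",   "RRE"),
    c("RevErbA", "Cry1",    "RRE"))
  edges <- data.frame(
    source  = c(act[, 1], inh[, 1]),
    target  = c(act[, 2], inh[, 2]),
    mode    = rep(c("activation", "inhibition"), c(nrow(act), nrow(inh))),
    element = c(act[, 3], inh[, 3]),
    stringsAsFactors = FALSE)
  if (length(exponents) == 1L) exponents <- rep(exponents, nrow(edges))
  stopifnot(length(exponents) == nrow(edges), all(exponents >= 1))
  edges$n <- as.numeric(exponents)
  topo <- structure(list(genes = genes, edges = edges),
                    class = "clock_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  stopifnot(inherits(topo, "clock_topology"))
  e <- topo$edges
  if (anyDuplicated(e[, c("source", "target", "element")]))
    stop("duplicate (source, target, element) regulation")
  if (!all(e$source %in% topo$genes) || !all(e$target %in% topo$genes))
    stop("edge endpoints must be genes of the topology")
  if (!all(topo$genes %in% e$target))
    stop("every gene must have at least one incoming regulation")
  if (any(e$n < 1)) stop("exponents must be >= 1")
  invisible(topo)
}

#' @export
print.clock_topology <- function(x, ...) {
  cat("Clock network topology:", length(x$genes), "genes,",
      nrow(x$edges), "regulations (",
      sum(x$edges$mode == "activation"), "activations,",
      sum(x$edges$mode == "inhibition"), "inhibitions )\n")
  invisible(x)
}

#' Read/write a topology as a plain-text edge list
#'
#' Serializes the regulation graph as a TSV with columns
#' `source`, `target`, `mode`, `element`, `n` so exponent tables can be
#' maintained outside the code.
#'
#' @param topo A `clock_topology`.
#' @param path File path.
#' @return `read_topology` returns a `clock_topology`.
#' @export
write_topology <- function(topo, path) {
  validate_topology(topo)
  utils::write.table(topo$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  topo <- structure(list(genes = clock_genes(), edges = e),
                    class = "clock_topology")
  validate_topology(topo)
  topo
}

# Internal: integer codes used by the C++ integrator (0-based).
topology_codes <- function(topo) {
  genes <- topo$genes
  e <- topo$edges
  list(source = match(e$source, genes) - 1L,
       target = match(e$target, genes) - 1L,
       type   = ifelse(e$mode == "inhibition", 1L, 0L),
       n      = e$n)
}

#' Names of the flattened kinetic parameter vector
#'
#' The 34 kinetic parameters are flattened in a fixed, documented order:
#' activation folds `a` (one per activation edge, edge order), activation
#' thresholds `K` (same order), inhibition strengths `r` (inhibition edge
#' order), degradation rates `d` (gene order), delays `tau` (gene order;
#' one delay per regulator, shared by all its outgoing edges).
#'
#' @param topo A `clock_topology`.
#' @return Character vector of parameter names (length 34 for the default
#'   topology).
#' @export
parameter_names <- function(topo = default_topology()) {
  e <- topo$edges
  acts <- e[e$mode == "activation", ]
  inhs <- e[e$mode == "inhibition", ]
  c(paste0("a_", acts$source, ".", acts$target),
    paste0("K_", acts$source, ".", acts$target),
    paste0("r_", inhs$source, ".", inhs$target),
    paste0("d_", topo$genes),
    paste0("tau_", topo$genes))
}

#' Construct a parameter set for a topology
#'
#' @param x Named or unnamed numeric vector in the flattening order of
#'   [parameter_names()].
#' @param topo A `clock_topology`.
#' @return A named numeric vector of class `clock_params`.
#' @export
clock_params <- function(x, topo = default_topology()) {
  nm <- parameter_names(topo)
  if (length(x) != length(nm))
    stop("expected ", length(nm), " parameters, got ", length(x))
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm)) stop("parameter names do not match topology")
    x <- x[nm]
  } else names(x) <- nm
  structure(as.numeric(stats::setNames(x, nm)), names = nm,
            class = "clock_params")
}

# Internal: split a flat parameter vector into the pieces the integrator needs.
split_params <- function(params, topo) {
  e <- topo$edges
  na <- sum(e$mode == "activation")
  ni <- sum(e$mode == "inhibition")
  G <- length(topo$genes)
  p <- as.numeric(params)
  a_act <- p[seq_len(na)]
  K_act <- p[na + seq_len(na)]
  r_inh <- p[2 * na + seq_len(ni)]
  d <- p[2 * na + ni + seq_len(G)]
  tau <- p[2 * na + ni + G + seq_len(G)]
  # expand to per-edge vectors aligned with edge order
  a <- K <- r <- rep(NA_real_, nrow(e))
  a[e$mode == "activation"] <- a_act
  K[e$mode == "activation"] <- K_act
  r[e$mode == "inhibition"] <- r_inh
  list(a = a, K = K, r = r, d = d, tau = tau)
}

#' Box bounds of the kinetic parameters
#'
#' Biologically motivated search ranges: activation folds in \[1, 50\],
#' thresholds in \[0.05, 5\] mean-normalized units, inhibition strengths in
#' \[0.1, 20\] inverse units (working points near the normalized mean of 1),
#' degradation rates in \[0.05, 1\] per hour (mRNA half-lives of roughly
#' 0.7 to 14 h), the Bmal1 delay in \[0, 6\] h and other delays in
#' \[0, 12\] h.
#'
#' @param topo A `clock_topology`.
#' @param tau_bmal1_max Upper bound of the Bmal1 delay in hours.
#' @param tau_max Upper bound of the other delays in hours.
#' @return A list with numeric vectors `lower` and `upper`, named and ordered
#'   as [parameter_names()].
#' @export
parameter_bounds <- function(topo = default_topology(),
                             tau_bmal1_max = 6, tau_max = 12) {
  nm <- parameter_names(topo)
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  is_a <- startsWith(nm, "a_"); is_K <- startsWith(nm, "K_")
  is_r <- startsWith(nm, "r_"); is_d <- startsWith(nm, "d_")
  is_t <- startsWith(nm, "tau_")
  lower[is_a] <- 1;    upper[is_a] <- 50
  lower[is_K] <- 0.05; upper[is_K] <- 5
  lower[is_r] <- 0.1;  upper[is_r] <- 20
  lower[is_d] <- 0.05; upper[is_d] <- 1.0
  lower[is_t] <- 0;    upper[is_t] <- tau_max
  upper["tau_Bmal1"] <- tau_bmal1_max
  list(lower = lower, upper = upper)
}
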