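#' Enumerate all simple directed cycles of a topology
#'
#' Depth-first enumeration of every simple directed cycle of the
#' regulation graph, each annotated with its sign (negative iff the number
#' of inhibition edges is odd).  Cycles are canonically rotated to start at
#' their lowest-index gene and sorted deterministically.
#'
#' @param topo A `clock_topology`.
#' @return A list of `clock_loop` objects: lists with `genes` (ordered
#'   cycle, first gene repeated implicitly), `edges` (row indices into
#'   `topo$edges`), `sign` ("negative"/"positive"), `length`.
#' @export
enumerate_loops <- function(topo = default_topology()) {
  genes <- topo$genes
  e <- topo$edges
  G <- length(genes)
  # adjacency: out[[i]] = list of (edge index, target index)
  src_i <- match(e$source, genes); tgt_i <- match(e$target, genes)
  out <- lapply(seq_len(G), function(i) which(src_i == i))
  loops <- list()
  # cycles whose minimal gene index is `start` begin (and end) at `start`
  for (start in seq_len(G)) {
    path_nodes <- integer(0); path_edges <- integer(0)
    visit <- function(v) {
      for (ei in out[[v]]) {
        w <- tgt_i[ei]
        if (w == start) {
          loops[[length(loops) + 1L]] <<- list(
            nodes = c(start, path_nodes), edges = c(path_edges, ei))
        } else if (w > start && !(w %in% path_nodes)) {
          path_nodes <<- c(path_nodes, w)
          path_edges <<- c(path_edges, ei)
          visit(w)
          path_nodes <<- path_nodes[-length(path_nodes)]
          path_edges <<- path_edges[-length(path_edges)]
        }
      }
    }
    visit(start)
  }
  loops <- lapply(loops, function(l) {
    n_inh <- sum(e$mode[l$edges] == "inhibition")
    structure(list(genes = genes[l$nodes], edges = l$edges,
                   sign = if (n_inh %% 2 == 1) "negative" else "positive",
                   length = length(l$edges)),
              class = "clock_loop")
  })
  ord <- order(vapply(loops, function(l) l$length, numeric(1)),
               vapply(loops, function(l) paste(l$genes, collapse = ">"),
                      character(1)))
  loops[ord]
}

#' @export
print.clock_loop <- function(x, ...) {
  cat(paste(c(x$genes, x$genes[1]), collapse = " -> "),
      sprintf("[%s, length %d]\n", x$sign, x$length))
  invisible(x)
}

# Internal: does loop l consist exactly of the gene sequence `seq` (as a
# rotation-invariant match)?
loop_matches <- function(l, genes_seq) {
  if (length(l$genes) != length(genes_seq)) return(FALSE)
  k <- length(genes_seq)
  any(vapply(seq_len(k), function(r)
    identical(l$genes, genes_seq[((seq_len(k) + r - 2) %% k) + 1]),
    logical(1)))
}

#' Catalog of the four core loop families
#'
#' The four negative feedback loops most prominent in the analysis and in
#' the literature: the Per2 and Cry1 self-inhibitions (each counted
#' together with its extension through Dbp), the Bmal1/Rev-erb-alpha loop,
#' and the repressilator (the serial inhibition chain
#' Per2 -| RevErbA -| Cry1 -| Per2).
#'
#' @param topo A `clock_topology` (default topology expected).
#' @return Named list of families; each family is a list of member
#'   `clock_loop`s.
#' @export
core_loop_catalog <- function(topo = default_topology()) {
  loops <- enumerate_loops(topo)
  find <- function(seqs) {
    members <- list()
    for (sq in seqs) {
      hit <- Filter(function(l) loop_matches(l, sq), loops)
      members <- c(members, hit)
    }
    members
  }
  fam <- list(
    Per2_loop    = find(list("Per2", c("Per2", "Dbp"))),
    Cry1_loop    = find(list("Cry1", c("Cry1", "Dbp"))),
    Bmal1_RevErbA = find(list(c("Bmal1", "RevErbA"))),
    Repressilator = find(list(c("Per2", "RevErbA", "Cry1"))))
  empty <- names(fam)[vapply(fam, length, integer(1)) == 0]
  if (length(empty)) {
    warning("topology lacks loop families: ", paste(empty, collapse = ", "))
    fam <- fam[setdiff(names(fam), empty)]
  }
  fam
}

#' Clamp constants along a fitted limit cycle
#'
#' For each gene, the mean expression over the final cycles of the base
#' trajectory; for each regulation, the time-average of its fold factor
#' over one period of the base trajectory (the constant that replaces the
#' term when the regulation is clamped).
#'
#' @param traj Unclamped `clock_trajectory` of the fitted model.
#' @param params,topo Model.
#' @param transient Hours discarded before averaging.
#' @param reference Reference gene for the period.
#' @return List with `gene_means` (named), `edge_means` (length = number of
#'   edges), `period`, `rhythmic`.
#' @export
clamp_constants <- function(traj, params, topo = default_topology(),
                            transient = 480, reference = "Bmal1") {
  feats <- extract_features(traj, reference = reference,
                            transient = transient)
  t_end <- max(traj$times)
  window_start <- if (feats$rhythmic) t_end - feats$period else transient
  # half-open window: with periodic dynamics the closed window would count
  # the cycle boundary twice and bias the means
  keep <- traj$times >= window_start & traj$times < t_end
  gene_means <- colMeans(traj$values[keep, , drop = FALSE])
  edge_means <- vapply(seq_len(nrow(topo$edges)), function(i)
    mean(edge_factor_series(traj, i, params, topo)[keep]), numeric(1))
  list(gene_means = gene_means, edge_means = edge_means,
       period = feats$period, rhythmic = feats$rhythmic)
}

#' Simulate a clamped variant of a fitted model
#'
#' Re-simulates the model with the requested genes frozen at their
#' limit-cycle means and/or the requested regulation terms replaced by
#' their limit-cycle average factors.
#'
#' @param params,topo Model.
#' @param constants Output of [clamp_constants()].
#' @param genes Character vector of genes to clamp (may be empty).
#' @param edges Integer vector of edge indices to clamp (may be empty).
#' @param duration,step Simulation controls.
#' @return A `clock_trajectory`.
#' @export
clamp_simulate <- function(params, topo, constants, genes = character(0),
                           edges = integer(0), duration = 720, step = 0.05) {
  gc <- NULL
  if (length(genes)) gc <- constants$gene_means[genes]
  ec <- rep(NA_real_, nrow(topo$edges))
  if (length(edges)) ec[edges] <- constants$edge_means[edges]
  simulate_clock(params, topo, duration = duration, step = step,
                 gene_clamp = gc, edge_clamp = ec)
}

# Internal: default rhythmicity criterion used by the loop analysis.
rhythm_criterion <- function(transient = 480, epsilon = 0.01,
                             decay_min = 0.95) {
  list(transient = transient, epsilon = epsilon, decay_min = decay_min)
}

#' Loop dissection of a fitted clock model
#'
#' Runs the full clamping analysis of one fitted parameter set:
#' every single regulation is clamped in turn (a negative feedback loop is
#' *essential* when every one of its edges, clamped alone, abolishes
#' sustained rhythmicity), and every subset of the core loop families is
#' tested for *sufficiency* by clamping all regulations outside the subset
#' (minimal sufficient subsets are the "rhythm-generating oscillators").
#' Synergy of a multi-loop oscillator is classified as `independent` when
#' at least two of its single loops are sufficient alone, `dependent`
#' otherwise.
#'
#' @param fit A `clock_fit`, or a `clock_params` vector.
#' @param topo A `clock_topology`.
#' @param duration,step,transient Simulation controls.
#' @param criterion Rhythmicity criterion (see [is_rhythmic()]).
#' @param catalog Core loop families from [core_loop_catalog()].
#' @return A `clock_loop_report`: list with `essential_families`,
#'   `essential_members`, `edge_rhythmic` (verdict per single-edge clamp),
#'   `minimal_oscillators` (list of family-name vectors), `sufficient_sets`,
#'   `synergy` (per minimal oscillator), `constants`, `criterion`,
#'   `period`, `score` (if a fit was given).
#' @export
loop_report <- function(fit, topo = default_topology(), duration = 720,
                        step = 0.05, transient = 480,
                        criterion = rhythm_criterion(transient),
                        catalog = core_loop_catalog(topo)) {
  params <- if (inherits(fit, "clock_fit")) fit$params else fit
  base <- simulate_clock(params, topo, duration = duration, step = step)
  if (!is_rhythmic(base, transient = criterion$transient,
                   epsilon = criterion$epsilon,
                   decay_min = criterion$decay_min))
    stop("unclamped model is not rhythmic; loop dissection undefined")
  constants <- clamp_constants(base, params, topo, transient = transient)
  ne <- nrow(topo$edges)
  check <- function(genes = character(0), edges = integer(0)) {
    tr <- clamp_simulate(params, topo, constants, genes, edges,
                         duration = duration, step = step)
    is_rhythmic(tr, transient = criterion$transient,
                epsilon = criterion$epsilon,
                decay_min = criterion$decay_min)
  }
  edge_rhythmic <- vapply(seq_len(ne), function(i) check(edges = i),
                          logical(1))
  member_essential <- lapply(catalog, function(members)
    vapply(members, function(l) all(!edge_rhythmic[l$edges]), logical(1)))
  essential_families <- names(catalog)[vapply(member_essential, any,
                                              logical(1))]
  # sufficiency over family subsets: clamp everything outside the subset
  fam_names <- names(catalog)
  fam_edges <- lapply(catalog, function(members)
    sort(unique(unlist(lapply(members, function(l) l$edges)))))
  subsets <- unlist(lapply(seq_along(fam_names), function(k)
    utils::combn(fam_names, k, simplify = FALSE)), recursive = FALSE)
  sufficient <- vapply(subsets, function(S) {
    keep_edges <- sort(unique(unlist(fam_edges[S])))
    check(edges = setdiff(seq_len(ne), keep_edges))
  }, logical(1))
  suff_sets <- subsets[sufficient]
  minimal <- Filter(function(S) {
    !any(vapply(suff_sets, function(S2)
      length(S2) < length(S) && all(S2 %in% S), logical(1)))
  }, suff_sets)
  synergy <- vapply(minimal, function(S) {
    if (length(S) < 2) return(NA_character_)
    classify_synergy_sets(S, suff_sets)
  }, character(1))
  structure(list(
    essential_families = essential_families,
    essential_members = member_essential,
    edge_rhythmic = edge_rhythmic,
    minimal_oscillators = minimal,
    sufficient_sets = suff_sets,
    synergy = synergy,
    constants = constants,
    criterion = criterion,
    period = constants$period,
    score = if (inherits(fit, "clock_fit")) fit$score$total else NA_real_,
    tissue = if (inherits(fit, "clock_fit")) fit$tissue else NA_character_,
    duration = duration, step = step), class = "clock_loop_report")
}

# Internal: synergy label given the list of all sufficient family sets.
classify_synergy_sets <- function(S, suff_sets) {
  singles <- vapply(S, function(f)
    any(vapply(suff_sets, function(S2) identical(S2, f), logical(1))),
    logical(1))
  if (sum(singles) >= 2) "independent" else "dependent"
}

#' Synergy classification of a sufficient loop set
#'
#' `independent` when at least two of the set's single loops are each
#' sufficient on their own (the loops mutually compensate); `dependent`
#' when no proper subset is sufficient (the loops share the required
#' feedback).
#'
#' @param report A `clock_loop_report`.
#' @param oscillator Character vector of >= 2 family names.
#' @return `"independent"` or `"dependent"`.
#' @export
classify_synergy <- function(report, oscillator) {
  stopifnot(inherits(report, "clock_loop_report"))
  if (length(oscillator) < 2)
    stop("synergy is undefined for a single loop")
  classify_synergy_sets(oscillator, report$sufficient_sets)
}

#' Essential core loops of a fitted model
#'
#' Convenience wrapper around [loop_report()] returning just the names of
#' the essential core families.
#'
#' @inheritParams loop_report
#' @return Character vector of essential family names.
#' @export
essential_loops <- function(fit, topo = default_topology(), ...) {
  loop_report(fit, topo, ...)$essential_families
}

#' @export
print.clock_loop_report <- function(x, ...) {
  cat("Loop dissection report\n")
  cat("  essential families:",
      if (length(x$essential_families))
        paste(x$essential_families, collapse = ", ") else "(none)", "\n")
  cat("  minimal oscillators:",
      if (length(x$minimal_oscillators))
        paste(vapply(x$minimal_oscillators, paste, character(1),
                     collapse = "+"), collapse = "; ") else "(none)", "\n")
  invisible(x)
}

#' Re-verify a loop report by direct simulation
#'
#' Re-runs the single-edge clamps and the minimal-oscillator sufficiency
#' clamps recorded in a report and checks that the verdicts reproduce.
#'
#' @param report A `clock_loop_report`.
#' @param params,topo Model the report was computed from.
#' @return `TRUE` (invisibly) if all verdicts reproduce; otherwise an error.
#' @export
verify_loop_report <- function(report, params, topo = default_topology()) {
  ne <- nrow(topo$edges)
  crit <- report$criterion
  for (i in seq_len(ne)) {
    tr <- clamp_simulate(params, topo, report$constants, edges = i,
                         duration = report$duration, step = report$step)
    v <- is_rhythmic(tr, transient = crit$transient,
                     epsilon = crit$epsilon, decay_min = crit$decay_min)
    if (!identical(v, report$edge_rhythmic[i]))
      stop("edge-clamp verdict ", i, " failed to reproduce")
  }
  invisible(TRUE)
}
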