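#' Read a gene-by-time expression table
#'
#' Reads a TSV/CSV with gene names in the first column and sampling times
#' (hours) in the header, validates that the five core clock genes are
#' present (case-insensitive, with common aliases: Arntl = Bmal1;
#' Nr1d1, Reverba, Rev-erb-a, Rev-erb-alpha = RevErbA), and
#' mean-normalizes.
#'
#' @param path File path.
#' @param tissue Tissue label (default: file name without extension).
#' @param sep Field separator (`"\t"` or `","`; guessed from extension).
#' @return A `clock_profile`.
#' @export
read_expression_table <- function(path, tissue = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(tissue))
    tissue <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes_raw <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric values in column(s): ",
         paste(names(df[-1])[bad], collapse = ", "))
  }
  times <- suppressWarnings(as.numeric(colnames(vals)))
  if (anyNA(times)) stop("header must give sampling times in hours")
  canonical <- canonical_gene_names(genes_raw)
  missing <- setdiff(clock_genes(), canonical)
  if (length(missing))
    stop("missing gene(s): ", paste(missing, collapse = ", "),
         " (found: ", paste(genes_raw, collapse = ", "), ")")
  rownames(vals) <- canonical
  vals <- vals[clock_genes(), , drop = FALSE]
  normalize_profile(vals, times, tissue = tissue)
}

canonical_gene_names <- function(x) {
  alias <- c(bmal1 = "Bmal1", arntl = "Bmal1",
             dbp = "Dbp",
             per2 = "Per2",
             cry1 = "Cry1",
             reverba = "RevErbA", nr1d1 = "RevErbA",
             "rev-erba" = "RevErbA", "rev-erb-a" = "RevErbA",
             "rev-erb-alpha" = "RevErbA", "rev-erb-α" = "RevErbA")
  key <- tolower(trimws(x))
  out <- alias[key]
  ifelse(is.na(out), x, out)
}

#' Write an expression profile as a TSV table
#'
#' @param profile A `clock_profile`.
#' @param path Output path.
#' @export
write_expression_table <- function(profile, path) {
  stopifnot(inherits(profile, "clock_profile"))
  # full-precision decimal formatting so write -> read -> write is a
  # byte-identical fixed point
  vals <- apply(profile$values, c(1, 2), function(x) sprintf("%.17g", x))
  df <- data.frame(gene = profile$genes, vals, check.names = FALSE)
  colnames(df) <- c("gene", profile$times)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.clockloops_format_version <- "1"

#' Persist and reload fit results
#'
#' Fit results round-trip losslessly through a JSON file carrying a format
#' version tag; an unknown tag is an explicit error.
#'
#' @param fit A `clock_fit`.
#' @param path File path.
#' @return `read_fit` returns a `clock_fit`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "clock_fit"))
  obj <- list(format = "clockloops_fit",
              version = .clockloops_format_version,
              params = as.list(unclass(fit$params)),
              score = fit$score$total,
              score_breakdown = as.list(fit$score$breakdown),
              trace = fit$trace, tissue = fit$tissue, seed = fit$seed,
              vfo_used = fit$vfo_used, vfo_residual = fit$vfo_residual,
              config = unclass(fit$config),
              duration = fit$duration, step = fit$step,
              transient = fit$transient, tol = fit$tol)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupted fit file: ", path))
  if (!identical(obj$format, "clockloops_fit") ||
      !identical(obj$version, .clockloops_format_version))
    stop("incompatible fit file (format/version mismatch): ", path)
  params <- clock_params(unlist(obj$params))
  score <- structure(list(total = obj$score,
                          breakdown = unlist(obj$score_breakdown),
                          nonrhythmic = obj$score >= obj$tol$penalty_nonrhythmic),
                     class = "clock_score")
  structure(list(params = params, score = score, trace = obj$trace,
                 tissue = obj$tissue, seed = obj$seed,
                 vfo_used = obj$vfo_used, vfo_residual = obj$vfo_residual,
                 config = structure(as.list(obj$config),
                                    class = "swarm_config"),
                 duration = obj$duration, step = obj$step,
                 transient = obj$transient,
                 tol = as.list(obj$tol)),
            class = "clock_fit")
}

#' Persist and reload loop reports
#'
#' @param report A `clock_loop_report`.
#' @param path File path.
#' @return `read_loop_report` returns a `clock_loop_report`.
#' @export
write_loop_report <- function(report, path) {
  stopifnot(inherits(report, "clock_loop_report"))
  obj <- c(list(format = "clockloops_loop_report",
                version = .clockloops_format_version),
           unclass(report))
  obj$essential_members <- lapply(obj$essential_members, as.logical)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_loop_report
#' @export
read_loop_report <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupted report file: ", path))
  if (!identical(obj$format, "clockloops_loop_report") ||
      !identical(obj$version, .clockloops_format_version))
    stop("incompatible loop-report file: ", path)
  obj$format <- NULL; obj$version <- NULL
  obj$minimal_oscillators <- lapply(obj$minimal_oscillators, as.character)
  obj$sufficient_sets <- lapply(obj$sufficient_sets, as.character)
  obj$constants$gene_means <- unlist(obj$constants$gene_means)
  structure(obj, class = "clock_loop_report")
}
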