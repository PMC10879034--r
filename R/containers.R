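#' progdecon: gene program decomposition, projection and cohort statistics
#'
#' Tools for decomposing nonnegative gene expression matrices into gene
#' programs by NMF, projecting a fixed gene-feature basis onto new datasets
#' with quality metrics, transferring a basis across species, and fitting the
#' cohort-level GLMs that detect quantitative (cell-frequency) and qualitative
#' (program-activity) changes across disease conditions.
#'
#' @keywords internal
"_PACKAGE"

#' Construct an expression matrix container
#'
#' A nonnegative genes x columns matrix with identifier axes. Columns are
#' cells for single-cell data or samples for bulk data. This is the canonical
#' orientation used throughout the package: `X = W %*% H` with genes indexing
#' rows of both `X` and the basis `W`.
#'
#' @param values Numeric matrix, genes in rows, columns (cells/samples) in
#'   columns. All values must be finite and nonnegative.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#' @param column_ids Character vector of unique column identifiers. Defaults
#'   to `colnames(values)`.
#' @param value_kind One of `"raw_count"`, `"cp10k_log"`, `"tpm"`, `"other"`;
#'   records what the values are so downstream steps can warn on mismatch.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (dense matrix with dimnames), `gene_ids`, `column_ids`,
#'   `value_kind`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              column_ids = colnames(values),
                              value_kind = c("raw_count", "cp10k_log", "tpm", "other")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(column_ids)) column_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  column_ids <- as.character(column_ids)
  if (length(gene_ids) != nrow(values))
    stop("format error: ", length(gene_ids), " gene identifiers for ",
         nrow(values), " rows", call. = FALSE)
  if (length(column_ids) != ncol(values))
    stop("format error: ", length(column_ids), " column identifiers for ",
         ncol(values), " columns", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("format error: duplicate gene identifiers (e.g. '",
         gene_ids[duplicated(gene_ids)][1L], "')", call. = FALSE)
  if (anyDuplicated(column_ids))
    stop("format error: duplicate column identifiers (e.g. '",
         column_ids[duplicated(column_ids)][1L], "')", call. = FALSE)
  if (any(!is.finite(values)))
    stop("domain error: non-finite values in expression matrix", call. = FALSE)
  if (any(values < 0))
    stop("domain error: negative values in expression matrix", call. = FALSE)
  dimnames(values) <- list(gene_ids, column_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 column_ids = column_ids, value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d columns (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a gene program basis
#'
#' A nonnegative genes x components weight matrix `W` produced by NMF (or
#' loaded from disk). Component labels default to `NMF0 ... NMF{k-1}`.
#'
#' @param weights Numeric matrix, genes in rows, components in columns;
#'   finite and nonnegative.
#' @param gene_ids Unique gene identifiers, one per row.
#' @param component_ids Component labels; default `NMF0...NMF{k-1}`.
#' @param hvg_universe The gene set (highly variable genes) used when the
#'   basis was fit; must contain all `gene_ids`. Defaults to `gene_ids`.
#' @return An object of class `gene_program_basis`.
#' @export
gene_program_basis <- function(weights, gene_ids = rownames(weights),
                               component_ids = colnames(weights),
                               hvg_universe = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (ncol(weights) < 1L)
    stop("domain error: basis needs at least one component", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(weights)))
  if (is.null(component_ids)) component_ids <- paste0("NMF", seq_len(ncol(weights)) - 1L)
  gene_ids <- as.character(gene_ids)
  component_ids <- as.character(component_ids)
  if (length(gene_ids) != nrow(weights) || length(component_ids) != ncol(weights))
    stop("format error: identifier counts do not match basis dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("format error: duplicate gene identifiers in basis", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("domain error: non-finite weights in basis", call. = FALSE)
  if (any(weights < 0))
    stop("domain error: negative weights in basis", call. = FALSE)
  if (is.null(hvg_universe)) hvg_universe <- gene_ids
  hvg_universe <- as.character(hvg_universe)
  if (!all(gene_ids %in% hvg_universe))
    stop("format error: hvg_universe must contain every basis gene", call. = FALSE)
  dimnames(weights) <- list(gene_ids, component_ids)
  structure(list(weights = weights, gene_ids = gene_ids,
                 component_ids = component_ids, hvg_universe = hvg_universe),
            class = "gene_program_basis")
}

#' @export
print.gene_program_basis <- function(x, ...) {
  cat(sprintf("<gene_program_basis> %d genes x %d components [%s%s]\n",
              nrow(x$weights), ncol(x$weights),
              paste(utils::head(x$component_ids, 3L), collapse = ", "),
              if (length(x$component_ids) > 3L) ", ..." else ""))
  invisible(x)
}

#' Construct a program activity matrix
#'
#' The components x columns matrix `H` of per-cell (or per-sample) program
#' activities accompanying a basis `W`.
#'
#' @param values Nonnegative numeric matrix, components in rows.
#' @param component_ids,column_ids Axis identifiers.
#' @return An object of class `program_activity`.
#' @export
program_activity <- function(values, component_ids = rownames(values),
                             column_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(component_ids)) component_ids <- paste0("NMF", seq_len(nrow(values)) - 1L)
  if (is.null(column_ids)) column_ids <- paste0("c", seq_len(ncol(values)))
  component_ids <- as.character(component_ids)
  column_ids <- as.character(column_ids)
  if (length(component_ids) != nrow(values) || length(column_ids) != ncol(values))
    stop("format error: identifier counts do not match activity dimensions", call. = FALSE)
  if (any(!is.finite(values)))
    stop("domain error: non-finite values in activity matrix", call. = FALSE)
  if (any(values < 0))
    stop("domain error: negative values in activity matrix", call. = FALSE)
  dimnames(values) <- list(component_ids, column_ids)
  structure(list(values = values, component_ids = component_ids,
                 column_ids = column_ids),
            class = "program_activity")
}

#' @export
print.program_activity <- function(x, ...) {
  cat(sprintf("<program_activity> %d components x %d columns\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a homolog map
#'
#' An ordered list of (source symbol, target symbol) pairs used to rename
#' basis genes across species. Order is preserved exactly as supplied: when a
#' source gene has several homologs, the first pair in the table wins.
#'
#' @param source,target Character vectors of equal length.
#' @return A `homolog_map`: a data frame with columns `source`, `target`.
#' @export
homolog_map <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target))
    stop("format error: source/target lengths differ", call. = FALSE)
  if (anyNA(source) || anyNA(target) || any(source == "") || any(target == ""))
    stop("format error: missing field in homolog pair", call. = FALSE)
  structure(data.frame(source = source, target = target,
                       stringsAsFactors = FALSE),
            class = c("homolog_map", "data.frame"))
}

# Run expr with a transient RNG state seeded by `seed`; the caller's RNG
# stream is untouched, so seeded functions are pure in their seed argument.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
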