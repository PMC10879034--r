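#' Read an expression matrix from disk
#'
#' Reads either a Matrix Market triplet file with gene/column identifier
#' sidecars, or a single dense TSV/CSV with a header row and an identifier
#' column. Whatever the on-disk orientation, the result is always returned in
#' the package's canonical genes x columns orientation. Gzip-compressed files
#' (`.gz` suffix) are handled transparently.
#'
#' @param path Path to the matrix: a `.mtx(.gz)` triplet file (then `genes`
#'   and `columns` are required) or a dense `.tsv`/`.csv(.gz)` with
#'   identifiers in the first column and a header row.
#' @param genes,columns For Matrix Market input: paths to one-identifier-per-
#'   line sidecar files for the rows and columns of the `.mtx` file (before
#'   any reorientation). Ignored for dense input.
#' @param orientation `"genes_in_rows"` if the on-disk rows are genes,
#'   `"genes_in_columns"` if they are cells/samples (the result is transposed
#'   to canonical orientation).
#' @param value_kind What the stored values are; see [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, genes = NULL, columns = NULL,
                                   orientation = c("genes_in_rows", "genes_in_columns"),
                                   value_kind = "raw_count") {
  orientation <- match.arg(orientation)
  is_mtx <- grepl("\\.mtx(\\.gz)?$", path)
  if (is_mtx) {
    if (is.null(genes) || is.null(columns))
      stop("format error: .mtx input requires 'genes' and 'columns' sidecar files",
           call. = FALSE)
    m <- if (grepl("\\.gz$", path)) Matrix::readMM(gzfile(path)) else Matrix::readMM(path)
    m <- as.matrix(m)
    row_ids <- read_id_column(genes)
    col_ids <- read_id_column(columns)
    if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m))
      stop("format error: identifier sidecar lengths (", length(row_ids), ", ",
           length(col_ids), ") do not match matrix dimensions (",
           nrow(m), ", ", ncol(m), ")", call. = FALSE)
    rownames(m) <- row_ids
    colnames(m) <- col_ids
  } else {
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L && ncol(df) == 0L)
      stop("format error: empty matrix file '", path, "'", call. = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("format error: non-numeric entries in '", path, "'", call. = FALSE)
  }
  if (orientation == "genes_in_columns") m <- t(m)
  expression_matrix(m, value_kind = value_kind)
}

# One identifier per line (first tab-separated field kept, so 10x-style
# two-column features files are accepted).
read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1L), 1L)
}

#' Read a gene-feature basis from TSV
#'
#' Expects gene identifiers in the first column and component labels in the
#' header row: the serialization written by [write_gene_feature_matrix()].
#'
#' @param path Path to a TSV (optionally gzipped).
#' @param hvg_universe Optional gene set the basis was fit on.
#' @return A [gene_program_basis()].
#' @export
read_gene_feature_matrix <- function(path, hvg_universe = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("format error: empty basis file '", path, "'", call. = FALSE)
  gene_program_basis(as.matrix(df), hvg_universe = hvg_universe)
}

#' Write a gene-feature basis to TSV
#'
#' Writes genes in rows, components in the header, at 15 significant digits
#' so a write-read round trip reproduces the weights to ~1e-12.
#'
#' @param basis A [gene_program_basis()].
#' @param path Output path.
#' @export
write_gene_feature_matrix <- function(basis, path) {
  stopifnot(inherits(basis, "gene_program_basis"))
  w <- basis$weights
  df <- data.frame(gene = rownames(w),
                   formatted_num(w),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(w))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

formatted_num <- function(m, digits = 15L) {
  out <- apply(m, 2L, function(col) formatC(col, digits = digits, format = "g"))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  out
}

#' Read a two-column homolog table
#'
#' Reads (source symbol, target symbol) pairs, e.g. human-to-mouse homologs.
#' Row order is preserved exactly and duplicates are kept: the order decides
#' which homolog wins when a source gene maps to several targets (see
#' [convert_species_basis()]).
#'
#' @param path Path to a two-column TSV (optionally gzipped).
#' @param header Logical; whether the first line is a header to skip.
#' @return A [homolog_map()].
#' @export
read_homolog_table <- function(path, header = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  body <- if (header) nf[-1L] else nf
  if (length(body) && any(body != 2L))
    stop("format error: homolog table row with ", body[body != 2L][1L],
         " fields (expected 2)", call. = FALSE)
  if (length(body) == 0L) return(homolog_map(character(0L), character(0L)))
  df <- utils::read.table(path, header = header, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  homolog_map(df[[1L]], df[[2L]])
}

#' Write a result table to TSV/CSV
#'
#' Writes a data frame (or a matrix, with its rownames as a leading `id`
#' column) with stable column order and floats at 10 significant digits, so
#' output is deterministic across runs and round-trips within 1e-9.
#' The separator follows the file suffix (`.csv` gives commas, anything else
#' tabs).
#'
#' @param table Data frame with named columns, or a numeric matrix.
#' @param path Output path.
#' @param id_column Name for the rownames column when `table` is a matrix.
#' @export
write_table <- function(table, path, id_column = "id") {
  if (is.matrix(table)) {
    df <- data.frame(rownames(table) %||% as.character(seq_len(nrow(table))),
                     formatted_num(table, 10L),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c(id_column, colnames(table))
    table <- df
  } else {
    table <- as.data.frame(table)
    num <- vapply(table, is.double, logical(1L))
    table[num] <- lapply(table[num], formatC, digits = 10L, format = "g")
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(table, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a program activity matrix
#'
#' Components as rows, columns (cells/samples) as columns, matching the
#' `W %*% H` orientation.
#'
#' @param activity A [program_activity()].
#' @param path Output path.
#' @export
write_program_activity <- function(activity, path) {
  stopifnot(inherits(activity, "program_activity"))
  write_table(activity$values, path, id_column = "component")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
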