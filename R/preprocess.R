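#' Normalize columns to a fixed total and (optionally) log-transform
#'
#' Counts-per-N normalization: each nonzero column is rescaled so its sum
#' equals `target_sum` (1e4 gives CP10K, the convention for single-cell
#' counts), then optionally `log1p`-transformed. All-zero columns are left
#' unchanged.
#'
#' @param x An [expression_matrix()].
#' @param target_sum Positive total each column is scaled to; default `1e4`.
#' @param apply_log If `TRUE` (default), apply natural `log1p` elementwise
#'   after scaling.
#' @return An [expression_matrix()] with `value_kind` `"cp10k_log"` when the
#'   log is applied, `"other"` otherwise.
#' @export
normalize_and_log <- function(x, target_sum = 1e4, apply_log = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is.numeric(target_sum) || length(target_sum) != 1L || target_sum <= 0)
    stop("domain error: target_sum must be a positive number", call. = FALSE)
  v <- x$values
  cs <- colSums(v)
  nz <- cs > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, cs[nz] / target_sum, "/")
  if (apply_log) v <- log1p(v)
  expression_matrix(v, x$gene_ids, x$column_ids,
                    value_kind = if (apply_log) "cp10k_log" else "other")
}

#' Per-gene highly-variable-gene statistics
#'
#' Computes the dispersion-based HVG statistics on log-normalized data: the
#' values are back-transformed with `expm1`, the per-gene mean `m` and sample
#' variance `v` (denominator N-1) are taken on that scale, dispersion is
#' `d = v/m`, and the reported statistics are `log1p(m)` and `log(d)`. Genes
#' are then cut into `n_bins` equal-width bins of the reported mean and the
#' normalized dispersion is the within-bin z-score of the reported
#' dispersion. A gene is flagged highly variable when
#' `min_mean < log1p(m) < max_mean` and its normalized dispersion exceeds
#' `min_disp`.
#'
#' Genes with zero dispersion (constant or all-zero) have no defined
#' log-dispersion; they get normalized dispersion 0 and are never flagged.
#' Bins with a single gene or zero spread also yield z = 0.
#'
#' @param x_lognorm An [expression_matrix()] holding `log1p` of normalized
#'   values (see [normalize_and_log()]).
#' @param min_mean,max_mean Window on the reported (log1p) mean; defaults
#'   0.0125 and 3.
#' @param min_disp Normalized-dispersion cutoff; 0.1 for query datasets,
#'   0.5 when fitting a reference basis.
#' @param n_bins Number of equal-width mean bins; default 20.
#' @return A data frame of class `hvg_stats` with one row per gene: columns
#'   `gene`, `mean` (log1p scale), `dispersion` (log scale; `-Inf` when the
#'   raw dispersion is 0), `dispersion_norm`, `hvg_flag`.
#' @export
compute_hvg_stats <- function(x_lognorm, min_mean = 0.0125, max_mean = 3,
                              min_disp = 0.1, n_bins = 20L) {
  stopifnot(inherits(x_lognorm, "expression_matrix"))
  if (ncol(x_lognorm$values) < 2L)
    stop("domain error: need at least 2 columns to estimate variance", call. = FALSE)
  y <- expm1(x_lognorm$values)
  m <- rowMeans(y)
  v <- apply(y, 1L, stats::var)            # sample variance, N-1
  d <- ifelse(m > 0, v / m, 0)
  mean_rep <- log1p(m)
  disp_rep <- ifelse(d > 0, log(d), -Inf)

  bins <- cut(mean_rep, breaks = n_bins, include.lowest = TRUE)
  z <- numeric(length(d))
  ok <- is.finite(disp_rep)
  for (b in levels(bins)) {
    idx <- which(bins == b & ok)
    if (length(idx) < 2L) next
    s <- stats::sd(disp_rep[idx])
    if (s > 0) z[idx] <- (disp_rep[idx] - mean(disp_rep[idx])) / s
  }
  flag <- mean_rep > min_mean & mean_rep < max_mean & z > min_disp & ok
  structure(data.frame(gene = x_lognorm$gene_ids, mean = mean_rep,
                       dispersion = disp_rep, dispersion_norm = z,
                       hvg_flag = flag, stringsAsFactors = FALSE),
            class = c("hvg_stats", "data.frame"),
            params = list(min_mean = min_mean, max_mean = max_mean,
                          min_disp = min_disp, n_bins = n_bins))
}

# V(D)J segment gene prefixes of the TCR and IG loci; constant-region genes
# (TRBC, IGHM, ...) are deliberately not listed.
VDJ_PREFIXES <- c("TRAV", "TRAJ", "TRBV", "TRBD", "TRBJ", "TRGV", "TRGJ",
                  "TRDV", "TRDD", "TRDJ",
                  "IGHV", "IGHD", "IGHJ", "IGKV", "IGKJ", "IGLV", "IGLJ")

is_vdj_gene <- function(genes) {
  pat <- paste0("^(", paste(VDJ_PREFIXES, collapse = "|"), ")")
  grepl(pat, genes)
}

#' Select the top highly variable genes
#'
#' Takes the flagged genes from [compute_hvg_stats()], removes V(D)J segment
#' genes of the TCR/IG loci when requested (their variance reflects clonal
#' structure, not transcriptional programs), ranks the rest by normalized
#' dispersion (descending, ties broken by lexicographic gene identifier) and
#' returns the first `n_top`.
#'
#' @param stats An `hvg_stats` data frame.
#' @param n_top Number of genes to return; `Inf` disables the clamp. When
#'   fewer flagged genes are available than `n_top`, all are returned with a
#'   warning.
#' @param exclude_vdj Drop V(D)J genes (prefixes TRAV/TRBV/IGHV/... ) first.
#' @return Ordered character vector of gene identifiers.
#' @export
select_hvgs <- function(stats, n_top = 500L, exclude_vdj = TRUE) {
  stopifnot(inherits(stats, "hvg_stats"))
  if (!is.infinite(n_top) && (!is.numeric(n_top) || n_top <= 0))
    stop("domain error: n_top must be positive", call. = FALSE)
  pool <- stats[stats$hvg_flag, , drop = FALSE]
  if (exclude_vdj) pool <- pool[!is_vdj_gene(pool$gene), , drop = FALSE]
  ord <- order(-pool$dispersion_norm, pool$gene, method = "radix")
  pool <- pool[ord, , drop = FALSE]
  if (is.finite(n_top) && nrow(pool) < n_top)
    warning("only ", nrow(pool), " highly variable genes available (asked for ",
            n_top, ")", call. = FALSE)
  utils::head(pool$gene, n_top)
}

#' HVG presets
#'
#' Two parameterizations are used in practice: `"reference"` when fitting a
#' basis (min_disp = 0.5, no top-N clamp, V(D)J genes kept for counting but
#' typically removed upstream) and `"query"` when measuring how well a fixed
#' basis covers a new dataset (min_disp = 0.1, top 500 by normalized
#' dispersion, V(D)J excluded) — the latter feeds [compute_poh()].
#'
#' @param x_lognorm An [expression_matrix()] of log-normalized values.
#' @param preset `"reference"` or `"query"`.
#' @return Ordered character vector of HVG identifiers.
#' @export
hvg_preset <- function(x_lognorm, preset = c("query", "reference")) {
  preset <- match.arg(preset)
  if (preset == "query") {
    s <- compute_hvg_stats(x_lognorm, min_disp = 0.1)
    select_hvgs(s, n_top = 500L, exclude_vdj = TRUE)
  } else {
    s <- compute_hvg_stats(x_lognorm, min_disp = 0.5)
    select_hvgs(s, n_top = Inf, exclude_vdj = FALSE)
  }
}
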