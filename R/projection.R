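# Lawson-Hanson active-set nonnegative least squares for one right-hand
# side: min_{h >= 0} ||A h - b||^2. Exact at termination (KKT residual on
# the passive set ~ machine precision). Rank-deficient passive sets are
# handled by zeroing aliased coordinates, giving a well-defined solution.
nnls_solve <- function(A, b, max_outer = NULL) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  tol <- 1e-12 * max(abs(Atb), 1)
  x <- numeric(n)
  passive <- logical(n)
  if (is.null(max_outer)) max_outer <- 10L * n + 50L
  for (outer in seq_len(max_outer)) {
    grad <- Atb - drop(AtA %*% x)
    if (all(passive) || max(grad[!passive]) <= tol) break
    j <- which(!passive)[which.max(grad[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      qrp <- qr(A[, passive, drop = FALSE])
      sp <- qr.coef(qrp, b)
      sp[is.na(sp)] <- 0
      s[passive] <- sp
      if (min(s[passive]) > 0) {
        x <- s
        break
      }
      neg <- passive & (s <= 0)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
      if (!any(passive)) break
    }
  }
  pmax(x, 0)
}

#' Convert a gene-program basis to another species
#'
#' Renames basis genes through a homolog table. Each basis gene with at least
#' one homolog is renamed to the FIRST homolog appearing in table order (for
#' genes with multiple homologs, one is retained); genes with no homolog are
#' dropped. When two source genes map to the same target, the first source in
#' basis order is retained and the collision is recorded. Weights are never
#' altered.
#'
#' @param w A [gene_program_basis()].
#' @param map A [homolog_map()] (see [read_homolog_table()]).
#' @return A [gene_program_basis()] on target-species symbols, with
#'   attributes `dropped_genes` (no homolog) and `collisions` (sources losing
#'   a shared target).
#' @export
convert_species_basis <- function(w, map) {
  stopifnot(inherits(w, "gene_program_basis"), inherits(map, "homolog_map"))
  if (nrow(map) == 0L)
    stop("domain error: empty homolog map", call. = FALSE)
  idx <- match(w$gene_ids, map$source)        # first occurrence wins
  keep <- !is.na(idx)
  dropped <- w$gene_ids[!keep]
  new_ids <- map$target[idx[keep]]
  weights <- w$weights[keep, , drop = FALSE]
  dup <- duplicated(new_ids)
  collisions <- character(0L)
  if (any(dup)) {
    collisions <- w$gene_ids[keep][dup]
    weights <- weights[!dup, , drop = FALSE]
    new_ids <- new_ids[!dup]
  }
  if (length(new_ids) == 0L)
    stop("domain error: no basis gene has a homolog; resulting basis empty",
         call. = FALSE)
  uni_idx <- match(w$hvg_universe, map$source)
  universe <- unique(c(new_ids, map$target[uni_idx[!is.na(uni_idx)]]))
  out <- gene_program_basis(weights, gene_ids = new_ids,
                            component_ids = w$component_ids,
                            hvg_universe = universe)
  attr(out, "dropped_genes") <- dropped
  attr(out, "collisions") <- collisions
  out
}

#' Align a fixed basis and a query matrix on their shared genes
#'
#' Restricts both the basis and the query expression matrix to the
#' intersection of their gene sets, in query gene order — only overlapping
#' genes take part in the projection, and the basis is not renormalized after
#' subsetting. A warning is issued when fewer than `min_overlap_fraction` of
#' the basis genes are found in the query; fewer overlapping genes than
#' components is an error (the projection would be underdetermined).
#'
#' @param w A [gene_program_basis()] (after species conversion, if any).
#' @param x_query An [expression_matrix()].
#' @param min_overlap_fraction Overlap fraction of basis genes below which a
#'   warning is raised; default 0.5.
#' @return An object of class `aligned_basis`: list with `basis`, `query`
#'   (both gene-subset, identical order), `n_overlap_genes`,
#'   `overlap_fraction_of_basis`, `dropped_basis_genes`,
#'   `dropped_query_genes`, `warnings`.
#' @export
align_to_basis <- function(w, x_query, min_overlap_fraction = 0.5) {
  stopifnot(inherits(w, "gene_program_basis"), inherits(x_query, "expression_matrix"))
  shared <- intersect(x_query$gene_ids, w$gene_ids)    # query gene order
  k <- ncol(w$weights)
  if (length(shared) < k)
    stop("domain error: only ", length(shared), " overlapping gene(s) for ",
         k, " components; projection underdetermined", call. = FALSE)
  frac <- length(shared) / length(w$gene_ids)
  warnings <- character(0L)
  if (frac < min_overlap_fraction) {
    msg <- sprintf("only %.1f%% of basis genes found in query (threshold %.0f%%)",
                   100 * frac, 100 * min_overlap_fraction)
    warning(msg, call. = FALSE)
    warnings <- c(warnings, msg)
  }
  basis_sub <- gene_program_basis(w$weights[shared, , drop = FALSE],
                                  gene_ids = shared,
                                  component_ids = w$component_ids,
                                  hvg_universe = w$hvg_universe)
  query_sub <- expression_matrix(x_query$values[shared, , drop = FALSE],
                                 gene_ids = shared,
                                 column_ids = x_query$column_ids,
                                 value_kind = x_query$value_kind)
  structure(list(basis = basis_sub, query = query_sub,
                 n_overlap_genes = length(shared),
                 overlap_fraction_of_basis = frac,
                 dropped_basis_genes = setdiff(w$gene_ids, shared),
                 dropped_query_genes = setdiff(x_query$gene_ids, shared),
                 warnings = warnings),
            class = "aligned_basis")
}

#' Project a query onto a fixed gene-program basis
#'
#' The fixed-basis projection: for each query column `x`, the activity column
#' solves `min_{h >= 0} ||x - W h||^2` exactly by active-set nonnegative
#' least squares, with `W` held fixed (no refitting). The overall explained
#' variance of the projection is computed on the aligned gene slice with the
#' same formula as for a de-novo decomposition.
#'
#' @param aligned An `aligned_basis` from [align_to_basis()].
#' @return An object of class `nmf_projection`: list with `activity`
#'   ([program_activity()]), `evar_all`, `poh` (`NA` here; filled by
#'   [nmf_project()] when query HVGs are available), `n_overlap_genes`,
#'   `overlap_fraction_of_basis`, `warnings`.
#' @export
project_fixed_basis <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_basis"))
  wv <- aligned$basis$weights
  xv <- aligned$query$values
  k <- ncol(wv)
  warnings <- aligned$warnings
  if (qr(wv)$rank < k) {
    msg <- "aligned basis is rank-deficient; activities are not unique"
    warning(msg, call. = FALSE)
    warnings <- c(warnings, msg)
  }
  h <- apply(xv, 2L, function(col) nnls_solve(wv, col))
  if (k == 1L) h <- matrix(h, nrow = 1L)
  activity <- program_activity(h, component_ids = aligned$basis$component_ids,
                               column_ids = aligned$query$column_ids)
  structure(list(activity = activity,
                 evar_all = evar_all(xv, wv, h),
                 poh = NA_real_,
                 poh_low_quality = NA,
                 n_overlap_genes = aligned$n_overlap_genes,
                 overlap_fraction_of_basis = aligned$overlap_fraction_of_basis,
                 warnings = warnings),
            class = "nmf_projection")
}

#' @export
print.nmf_projection <- function(x, ...) {
  cat(sprintf("<nmf_projection> %d components x %d columns\n",
              nrow(x$activity$values), ncol(x$activity$values)))
  cat(sprintf("  overlap: %d genes (%.1f%% of basis); Evar_all = %.4f\n",
              x$n_overlap_genes, 100 * x$overlap_fraction_of_basis, x$evar_all))
  if (!is.na(x$poh))
    cat(sprintf("  POH = %.3f%s\n", x$poh,
                if (isTRUE(x$poh_low_quality)) "  [below 0.1: query variance poorly covered]" else ""))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Proportion of query HVGs covered by a basis (POH)
#'
#' `POH = |query HVGs in basis genes| / |query HVGs|`, the fraction of a
#' query dataset's highly variable genes that the fixed basis can represent.
#' Query HVGs should come from the `"query"` preset of [hvg_preset()] (top
#' 500 by normalized dispersion, V(D)J excluded). A POH below 0.1 — a
#' conservative threshold — signals variance the projection cannot capture.
#'
#' @param query_hvgs Nonempty character vector of query HVG identifiers.
#' @param w A [gene_program_basis()].
#' @param threshold Low-quality cutoff; default 0.1.
#' @param use_hvg_universe If `TRUE`, count membership against the basis's
#'   fit-time HVG universe instead of its retained gene rows.
#' @return POH in `[0, 1]`, with attributes `low_quality` (logical) and
#'   `threshold`.
#' @export
compute_poh <- function(query_hvgs, w, threshold = 0.1, use_hvg_universe = FALSE) {
  stopifnot(inherits(w, "gene_program_basis"))
  query_hvgs <- as.character(query_hvgs)
  if (length(query_hvgs) == 0L)
    stop("domain error: empty query HVG list", call. = FALSE)
  ref <- if (use_hvg_universe) w$hvg_universe else w$gene_ids
  poh <- sum(query_hvgs %in% ref) / length(query_hvgs)
  structure(poh, low_quality = poh < threshold, threshold = threshold)
}

#' One-call fixed-basis projection with quality metrics
#'
#' Convenience wrapper chaining species conversion (optional), query
#' normalization (optional; by default the caller controls the input scale —
#' raw counts and TPM are both used in practice), gene alignment, exact
#' nonnegative projection, and the POH quality metric computed from the
#' query's own HVGs.
#'
#' @param w A [gene_program_basis()].
#' @param x An [expression_matrix()] (query).
#' @param species_map Optional [homolog_map()] applied to the basis first.
#' @param normalize `"none"` (default) or `"cp10k_log"` to normalize the
#'   query to counts-per-10k and log1p before projecting.
#' @param min_overlap_fraction Passed to [align_to_basis()].
#' @param query_hvgs Optional precomputed query HVG list for POH. If `NULL`
#'   and the query has at least 2 columns, HVGs are derived with the
#'   `"query"` preset (on CP10K-log values, computed internally if needed).
#' @param poh Compute POH? Default `TRUE`.
#' @return An `nmf_projection` (see [project_fixed_basis()]) with `poh`
#'   filled in when computable.
#' @export
nmf_project <- function(w, x, species_map = NULL,
                        normalize = c("none", "cp10k_log"),
                        min_overlap_fraction = 0.5,
                        query_hvgs = NULL, poh = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(w, "gene_program_basis"), inherits(x, "expression_matrix"))
  if (!is.null(species_map)) w <- convert_species_basis(w, species_map)
  x_proj <- if (normalize == "cp10k_log") normalize_and_log(x) else x
  aligned <- align_to_basis(w, x_proj, min_overlap_fraction)
  res <- project_fixed_basis(aligned)
  if (poh) {
    if (is.null(query_hvgs) && ncol(x$values) >= 2L) {
      x_log <- if (x$value_kind == "cp10k_log") x else normalize_and_log(x)
      query_hvgs <- tryCatch(hvg_preset(x_log, "query"), error = function(e) NULL)
      if (length(query_hvgs) == 0L) query_hvgs <- NULL
    }
    if (!is.null(query_hvgs)) {
      p <- compute_poh(query_hvgs, w)
      res$poh <- as.numeric(p)
      res$poh_low_quality <- attr(p, "low_quality")
      if (attr(p, "low_quality"))
        res$warnings <- c(res$warnings,
                          sprintf("POH = %.3f below 0.1: query variability poorly represented by the basis", res$poh))
    }
  }
  res
}

#' Project new data with a fitted NMF model
#'
#' `predict` on an [fit_nmf()] object projects `newdata` onto the fitted
#' gene-program basis with `W` held fixed (see [nmf_project()]).
#'
#' @param object An `nmf_fit`.
#' @param newdata An [expression_matrix()].
#' @param ... Passed on to [nmf_project()].
#' @return An `nmf_projection`.
#' @export
predict.nmf_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$activity)
  nmf_project(object$basis, newdata, ...)
}
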