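# Nonnegative double SVD initialization (variant that replaces zeros with the
# matrix mean), followed by a small seeded multiplicative perturbation so that
# different seeds explore different local optima while one seed is exactly
# reproducible.
nndsvd_init <- function(x, k, seed, perturb = 1e-2) {
  n <- nrow(x); m <- ncol(x)
  s <- svd(x, nu = k, nv = k)
  w <- matrix(0, n, k)
  h <- matrix(0, k, m)
  w[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  h[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  if (k >= 2L) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn && nup * nvp > 0) {
        sig <- sqrt(s$d[j] * nup * nvp)
        w[, j] <- sig * up / nup
        h[j, ] <- sig * vp / nvp
      } else if (nun * nvn > 0) {
        sig <- sqrt(s$d[j] * nun * nvn)
        w[, j] <- sig * un / nun
        h[j, ] <- sig * vn / nvn
      }
    }
  }
  mu <- mean(x)
  w[w <= 0] <- mu
  h[h <= 0] <- mu
  with_seed(seed, {
    w <- w * (1 + perturb * stats::runif(length(w)))
    h <- h * (1 + perturb * stats::runif(length(h)))
  })
  list(w = w, h = h)
}

#' Fit a nonnegative matrix factorization of an expression matrix
#'
#' Decomposes a nonnegative genes x columns matrix `X` into a gene-feature
#' matrix `W` (genes x components; the gene programs) and an activity matrix
#' `H` (components x columns) minimizing the squared Frobenius loss
#' `||X - W H||^2` under nonnegativity, by HALS coordinate descent from a
#' nonnegative-double-SVD start. No regularization is applied. The fit is
#' deterministic for a fixed `seed`.
#'
#' The redundancy diagnostic `max_spearman` is the maximum inter-component
#' Spearman correlation between activity rows of `H`: once `k` exceeds the
#' number of real programs, components duplicate and their activities become
#' nearly identical. (Gene-weight columns of `W` are a poorer substrate for
#' this diagnostic: their ranks are dominated by the many near-zero weights,
#' which share residual-noise structure across components.)
#'
#' Components are relabeled `NMF0...NMF{k-1}` in decreasing order of
#' per-component explained variance (see [evar_component()]) so component
#' numbering is stable and interpretable.
#'
#' @param x An [expression_matrix()], typically normalized expression
#'   restricted to highly variable genes.
#' @param k Number of components, `1 <= k <= min(dim(x))`.
#' @param seed Integer seed controlling the initialization perturbation.
#' @param max_iter Maximum coordinate-descent iterations.
#' @param tol Relative decrease of the objective below which the fit is
#'   declared converged.
#' @return An object of class `nmf_fit` with elements `basis`
#'   ([gene_program_basis()]), `activity` ([program_activity()]),
#'   `diagnostics` (class `decomposition_diagnostics`: `k`, `rss_all`,
#'   `evar_all`, `rss_per_component`, `evar_per_component`, `max_spearman`,
#'   `converged`, `n_iter`), and `x` (the input).
#' @seealso [evar_all()], [scan_components()], [predict.nmf_fit()]
#' @examples
#' sim <- simulate_expression(simulate_basis(60, 3, overlap = 0.1, seed = 1),
#'                            n_columns = 40, noise_model = "none",
#'                            noise_scale = 0, seed = 1)
#' fit <- fit_nmf(sim$expression, k = 3, seed = 1)
#' fit$diagnostics$evar_all
#' @export
fit_nmf <- function(x, k, seed = 0L, max_iter = 1000L, tol = 1e-6) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != round(k))
    stop("domain error: k must be a positive integer", call. = FALSE)
  if (k > min(dim(v)))
    stop("domain error: k = ", k, " exceeds min(dim) = ", min(dim(v)), call. = FALSE)
  if (any(!is.finite(v)))
    stop("domain error: non-finite input", call. = FALSE)
  ssx <- sum(v^2)
  if (ssx == 0)
    stop("domain error: all-zero input matrix", call. = FALSE)

  init <- nndsvd_init(v, k, seed)
  w <- init$w; h <- init$h
  obj_prev <- Inf
  converged <- FALSE
  iter <- 0L
  # HALS coordinate descent: one nonnegative least-squares pass over the
  # columns of W, then the rows of H, per iteration. Unlike multiplicative
  # updates it reaches exact zeros, so unused weights do not linger.
  for (iter in seq_len(max_iter)) {
    a <- tcrossprod(v, h); b <- tcrossprod(h)
    for (c in seq_len(k)) if (b[c, c] > 0)
      w[, c] <- pmax(w[, c] + (a[, c] - w %*% b[, c]) / b[c, c], 0)
    a <- crossprod(w, v); b <- crossprod(w)
    for (c in seq_len(k)) if (b[c, c] > 0)
      h[c, ] <- pmax(h[c, ] + (a[c, ] - b[c, ] %*% h) / b[c, c], 0)
    obj <- sum((v - w %*% h)^2)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  rss_c <- vapply(seq_len(k), function(c)
    sum((v - tcrossprod(w[, c], h[c, ]))^2), numeric(1L))
  ord <- order(rss_c, method = "radix")      # ascending RSS = descending Evar
  w <- w[, ord, drop = FALSE]
  h <- h[ord, , drop = FALSE]
  rss_c <- rss_c[ord]
  comp_ids <- paste0("NMF", seq_len(k) - 1L)

  basis <- gene_program_basis(w, gene_ids = x$gene_ids, component_ids = comp_ids)
  activity <- program_activity(h, component_ids = comp_ids, column_ids = x$column_ids)
  rss_all <- sum((v - w %*% h)^2)
  diagnostics <- structure(list(
    k = k,
    rss_all = rss_all,
    evar_all = 1 - rss_all / ssx,
    rss_per_component = stats::setNames(rss_c, comp_ids),
    evar_per_component = stats::setNames(1 - rss_c / ssx, comp_ids),
    # redundancy measured on activity rows: duplicated programs have
    # near-identical activities, whereas gene-weight ranks are dominated by
    # the many near-zero weights and pick up shared noise structure
    max_spearman = if (k >= 2L)
      suppressWarnings(max_intercomponent_correlation(t(h))) else NA_real_,
    converged = converged,
    n_iter = iter
  ), class = "decomposition_diagnostics")

  structure(list(basis = basis, activity = activity, diagnostics = diagnostics,
                 x = x, seed = seed, call = match.call()),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("NMF fit: %d genes x %d columns, k = %d\n",
              nrow(x$basis$weights), ncol(x$activity$values), d$k))
  cat(sprintf("  explained variance (all components): %.4f\n", d$evar_all))
  cat(sprintf("  %s after %d iterations\n",
              if (d$converged) "converged" else "NOT converged", d$n_iter))
  invisible(x)
}

#' @export
summary.nmf_fit <- function(object, ...) {
  d <- object$diagnostics
  out <- list(k = d$k, evar_all = d$evar_all,
              evar_per_component = d$evar_per_component,
              max_spearman = d$max_spearman,
              converged = d$converged, n_iter = d$n_iter)
  class(out) <- "summary.nmf_fit"
  out
}

#' @export
print.summary.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF decomposition, k = %d\n", x$k))
  cat(sprintf("  Evar_all = %.4f; max inter-component Spearman = %s\n",
              x$evar_all,
              if (is.na(x$max_spearman)) "NA" else sprintf("%.3f", x$max_spearman)))
  cat("  per-component explained variance:\n")
  print(round(x$evar_per_component, 4L))
  invisible(x)
}

#' @describeIn fit_nmf the gene-feature matrix `W` (genes x components).
#' @param object An `nmf_fit`.
#' @param ... Unused.
#' @export
coef.nmf_fit <- function(object, ...) object$basis$weights

#' @export
fitted.nmf_fit <- function(object, ...) {
  object$basis$weights %*% object$activity$values
}

#' @export
residuals.nmf_fit <- function(object, ...) {
  object$x$values - fitted(object)
}

as_values <- function(x) {
  if (inherits(x, "expression_matrix") || inherits(x, "program_activity")) x$values
  else if (inherits(x, "gene_program_basis")) x$weights
  else as.matrix(x)
}

#' Overall explained variance of a factorization
#'
#' `Evar_all = 1 - RSS_all / sum(X^2)` where
#' `RSS_all = sum((X - W %*% H)^2)`: the fraction of the total sum of squares
#' of `X` captured by the full reconstruction. It is 1 for an exact
#' factorization, 0 for the null model `H = 0`, and can be negative for a
#' reconstruction worse than the null.
#'
#' @param x Expression matrix (container or plain matrix), genes x columns.
#' @param w Gene-feature basis (container or matrix), genes x components.
#' @param h Activity (container or matrix), components x columns.
#' @return A single number `<= 1`.
#' @export
evar_all <- function(x, w, h) {
  xv <- as_values(x); wv <- as_values(w); hv <- as_values(h)
  if (nrow(wv) != nrow(xv) || ncol(hv) != ncol(xv) || ncol(wv) != nrow(hv))
    stop("domain error: non-conforming shapes", call. = FALSE)
  ssx <- sum(xv^2)
  if (ssx == 0) stop("domain error: all-zero expression matrix", call. = FALSE)
  1 - sum((xv - wv %*% hv)^2) / ssx
}

#' Per-component explained variance
#'
#' For component `c` of a joint fit, the rank-1 slice `w_c h_c` is treated as
#' a standalone reconstruction of `X`:
#' `RSS_c = sum((X - w_c %*% t(h_c))^2)` and `Evar_c = 1 - RSS_c / sum(X^2)`.
#' The slice comes from the jointly fitted `W, H`, not a per-component refit.
#'
#' @inheritParams evar_all
#' @param component Component index (1-based) or label.
#' @return A single number `<= 1`.
#' @export
evar_component <- function(x, w, h, component) {
  xv <- as_values(x); wv <- as_values(w); hv <- as_values(h)
  if (is.character(component)) {
    idx <- match(component, colnames(wv))
    if (is.na(idx)) stop("domain error: unknown component '", component, "'",
                         call. = FALSE)
  } else {
    idx <- component
    if (!is.numeric(idx) || idx < 1L || idx > ncol(wv))
      stop("domain error: component index out of range", call. = FALSE)
  }
  ssx <- sum(xv^2)
  if (ssx == 0) stop("domain error: all-zero expression matrix", call. = FALSE)
  1 - sum((xv - tcrossprod(wv[, idx], hv[idx, ]))^2) / ssx
}

#' Maximum inter-component Spearman correlation of a basis
#'
#' Redundancy diagnostic for rank selection: the maximum over all unordered
#' component pairs of the Spearman rank correlation between gene-feature
#' columns of `W`, with average ranks for ties. A sharp rise in this value as
#' `k` grows indicates components have started duplicating programs.
#'
#' @param w A [gene_program_basis()] or genes x components matrix with
#'   `k >= 2` columns.
#' @return Maximum pairwise Spearman correlation in `[-1, 1]`. Pairs
#'   involving a constant column are undefined and excluded with a warning.
#' @export
max_intercomponent_correlation <- function(w) {
  wv <- as_values(w)
  k <- ncol(wv)
  if (k < 2L)
    stop("domain error: need at least 2 components", call. = FALSE)
  rk <- apply(wv, 2L, rank)                # average ranks for ties
  const <- apply(wv, 2L, function(col) max(col) == min(col))
  if (any(const))
    warning(sum(const), " constant component column(s); pairs involving them excluded",
            call. = FALSE)
  keep <- which(!const)
  if (length(keep) < 2L) {
    warning("no valid component pair; returning NA", call. = FALSE)
    return(NA_real_)
  }
  cm <- stats::cor(rk[, keep, drop = FALSE])
  max(cm[upper.tri(cm)])
}

#' Top genes of a component
#'
#' Genes sorted by their weight in component `c`, descending, ties broken by
#' lexicographic gene identifier; the first `n` are returned. With the
#' default `n = 100` this is the conventional gene list fed to pathway
#' enrichment.
#'
#' @param w A [gene_program_basis()].
#' @param component Component index (1-based) or label.
#' @param n Number of genes; clamped to the number available.
#' @return Ordered character vector of gene identifiers.
#' @export
extract_top_genes <- function(w, component, n = 100L) {
  stopifnot(inherits(w, "gene_program_basis"))
  if (!is.numeric(n) || n < 1L)
    stop("domain error: n must be >= 1", call. = FALSE)
  if (is.character(component)) {
    idx <- match(component, w$component_ids)
    if (is.na(idx)) stop("domain error: unknown component '", component, "'",
                         call. = FALSE)
  } else {
    idx <- component
    if (idx < 1L || idx > ncol(w$weights))
      stop("domain error: component index out of range", call. = FALSE)
  }
  val <- w$weights[, idx]
  ord <- order(-val, w$gene_ids, method = "radix")
  utils::head(w$gene_ids[ord], n)
}

#' Scan candidate component numbers
#'
#' Fits an NMF per `k` and records the two rank-selection diagnostics: the
#' overall explained variance `Evar_all(k)` and the maximum inter-component
#' Spearman correlation. An advisory `k` is derived from the two usual visual
#' criteria: (i) `k` at or beyond the elbow of the `Evar_all` curve (the
#' point of maximum negative second difference) and (ii) `k` just before a
#' sharp increase (> `jump_threshold`) of the maximum inter-component
#' correlation. The advisory is the smallest scanned `k` meeting both (the
#' point just before redundancy sets in); it is
#' a suggestion for inspection, never auto-applied.
#'
#' @param x An [expression_matrix()] (normalized, HVG-restricted).
#' @param k_values Ascending integer vector of candidate `k`, each `>= 2`.
#' @param seed Seed passed to every [fit_nmf()] call.
#' @param jump_threshold Increase of max Spearman between consecutive scanned
#'   `k` counted as "sharp"; default 0.1.
#' @param ... Further arguments to [fit_nmf()] (`max_iter`, `tol`).
#' @return An object of class `nmf_scan`: a list with `summary` (data frame
#'   of `k`, `evar_all`, `max_spearman`, `converged`, `n_iter`),
#'   `diagnostics` (list of per-k `decomposition_diagnostics`) and
#'   `advisory_k` (integer or `NA` when no `k` meets both criteria or fewer
#'   than 3 values were scanned).
#' @export
scan_components <- function(x, k_values, seed = 0L, jump_threshold = 0.1, ...) {
  stopifnot(inherits(x, "expression_matrix"))
  k_values <- as.integer(k_values)
  if (is.unsorted(k_values, strictly = TRUE))
    stop("domain error: k_values must be strictly ascending", call. = FALSE)
  if (any(k_values < 2L))
    stop("domain error: scanned k must be >= 2", call. = FALSE)
  fits <- lapply(k_values, function(k) fit_nmf(x, k, seed = seed, ...)$diagnostics)
  evar <- vapply(fits, `[[`, numeric(1L), "evar_all")
  spear <- vapply(fits, `[[`, numeric(1L), "max_spearman")
  smry <- data.frame(k = k_values, evar_all = evar, max_spearman = spear,
                     converged = vapply(fits, `[[`, logical(1L), "converged"),
                     n_iter = vapply(fits, `[[`, integer(1L), "n_iter"))

  advisory <- NA_integer_
  nk <- length(k_values)
  if (nk >= 3L) {
    # elbow: scanned k with the most negative second difference of evar_all
    d2 <- evar[3:nk] - 2 * evar[2:(nk - 1L)] + evar[1:(nk - 2L)]
    elbow_k <- k_values[which.min(d2) + 1L]
    # sharp redundancy jump from k to the next scanned k
    jump <- diff(spear) > jump_threshold
    cand <- k_values[-nk][jump & k_values[-nk] >= elbow_k]
    if (length(cand)) advisory <- min(cand)
  }
  structure(list(summary = smry, diagnostics = fits, advisory_k = advisory,
                 jump_threshold = jump_threshold),
            class = "nmf_scan")
}

#' @export
print.nmf_scan <- function(x, ...) {
  cat("NMF component-number scan\n")
  print(transform(x$summary,
                  evar_all = round(evar_all, 4L),
                  max_spearman = round(max_spearman, 3L)), row.names = FALSE)
  if (is.na(x$advisory_k)) cat("advisory k: none (criteria not met)\n")
  else cat("advisory k:", x$advisory_k, "(inspect the curves before adopting)\n")
  invisible(x)
}

#' @export
plot.nmf_scan <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  plot(s$k, s$evar_all, type = "b", xlab = "k", ylab = "Evar_all",
       main = "Explained variance", ...)
  plot(s$k, s$max_spearman, type = "b", xlab = "k",
       ylab = "max inter-component Spearman", main = "Component redundancy", ...)
  if (!is.na(x$advisory_k)) graphics::abline(v = x$advisory_k, lty = 2L)
  invisible(x)
}
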