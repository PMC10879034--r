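# Independent oracles and small fixture builders shared across test files.

# Brute-force Benjamini-Hochberg step-up, written independently of
# stats::p.adjust: sort p ascending, q_(i) = min_{j >= i} p_(j) * n / j,
# capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * n / seq_len(n))
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Best rank-1 nonnegative approximation of a small matrix by dense grid over
# the unit-norm left factor followed by alternating local refinement. Given
# w >= 0 the optimal h is max(0, X'w / ||w||^2), elementwise nonnegative
# already for X >= 0.
rank1_oracle <- function(x, n_grid = 2000L, n_refine = 200L) {
  n <- nrow(x)
  best_obj <- Inf
  best <- NULL
  set.seed(1L)
  dirs <- matrix(abs(rnorm(n_grid * n)), n_grid, n)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in seq_len(n_grid)) {
    w <- dirs[i, ]
    h <- pmax(drop(crossprod(x, w)), 0)
    obj <- sum((x - outer(w, h))^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(w = w, h = h)
    }
  }
  w <- best$w; h <- best$h
  for (i in seq_len(n_refine)) {
    w <- pmax(drop(x %*% h), 0) / max(sum(h^2), 1e-300)
    h <- pmax(drop(crossprod(x, w)), 0) / max(sum(w^2), 1e-300)
  }
  sum((x - outer(w, h))^2)
}

# A small nonnegative count-like matrix with stable dimnames.
tiny_matrix <- function(nr = 4L, nc = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, 5), nr, nc,
              dimnames = list(paste0("g", seq_len(nr)), paste0("c", seq_len(nc))))
  m
}

# Log-normalized fixture on the expm1 scale: pass per-gene draws y >= 0 and
# get the log1p container compute_hvg_stats() expects.
lognorm_from_raw <- function(y, gene_ids = NULL) {
  m <- log1p(y)
  if (!is.null(gene_ids)) rownames(m) <- gene_ids
  expression_matrix(m, value_kind = "cp10k_log")
}

# Query-preset HVG fixture: Poisson background with gene-specific means
# spread over (0.5, 2) so CP10K-log means fall in the (0.0125, 3) window and
# every mean bin is well populated; one overdispersed planted gene plus
# overdispersed V(D)J decoys sitting mid-range of the mean distribution.
hvg_fixture <- function(n_genes = 2000L, n_cells = 300L, seed = 7L,
                        vdj = c("TRBV7", "IGHV1")) {
  set.seed(seed)
  lambda <- runif(n_genes, 0.5, 2)
  m <- matrix(rpois(n_genes * n_cells, rep(lambda, n_cells)), n_genes, n_cells)
  ids <- sprintf("G%05d", seq_len(n_genes))
  # planted gene: mean 1, ~10x the Poisson variance (gamma-poisson mixture)
  m[1L, ] <- rpois(n_cells, rgamma(n_cells, shape = 1 / 9, scale = 9))
  ids[1L] <- "PLANTED"
  for (i in seq_along(vdj)) {
    m[1L + i, ] <- rpois(n_cells, rgamma(n_cells, shape = 1 / 19, scale = 19))
    ids[i + 1L] <- vdj[i]
  }
  rownames(m) <- ids
  colnames(m) <- sprintf("c%04d", seq_len(n_cells))
  normalize_and_log(expression_matrix(m))
}
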