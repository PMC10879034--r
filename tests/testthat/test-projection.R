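test_that("species conversion renames through the first homolog and logs drops", {
  w <- gene_program_basis(matrix(1:6 / 10, 3L, 2L),
                          gene_ids = c("FOXP3", "A", "LOST"))
  map <- homolog_map(c("FOXP3", "A", "A"), c("Foxp3", "a1", "a2"))
  out <- convert_species_basis(w, map)
  expect_identical(out$gene_ids, c("Foxp3", "a1"))      # first homolog wins
  expect_identical(unname(out$weights), unname(w$weights[1:2, ]))
  expect_identical(attr(out, "dropped_genes"), "LOST")

  # target collision: first source in basis order keeps the name
  w2 <- gene_program_basis(matrix(1:4 / 10, 2L, 2L), gene_ids = c("X1", "X2"))
  map2 <- homolog_map(c("X1", "X2"), c("shared", "shared"))
  out2 <- convert_species_basis(w2, map2)
  expect_identical(out2$gene_ids, "shared")
  expect_identical(unname(out2$weights), unname(w2$weights[1L, , drop = FALSE]))
  expect_identical(attr(out2, "collisions"), "X2")

  expect_error(convert_species_basis(w, homolog_map("Z", "z")), "domain error")
  expect_error(convert_species_basis(w, homolog_map(character(0), character(0))),
               "domain error")
})

test_that("alignment restricts to the gene intersection with QC fields", {
  w <- gene_program_basis(matrix(runif(6), 3L, 2L), gene_ids = c("A", "B", "C"))
  x <- expression_matrix(matrix(1:8, 4L, 2L, dimnames =
                                list(c("B", "C", "D", "E"), c("s1", "s2"))))
  al <- suppressWarnings(align_to_basis(w, x))
  expect_identical(al$basis$gene_ids, c("B", "C"))
  expect_identical(al$query$gene_ids, c("B", "C"))
  expect_identical(al$dropped_basis_genes, "A")
  expect_identical(sort(al$dropped_query_genes), c("D", "E"))
  expect_equal(al$overlap_fraction_of_basis, 2 / 3)
  # low overlap warns but succeeds; disjoint sets fail
  expect_warning(align_to_basis(w, x, min_overlap_fraction = 0.9), "basis genes")
  bad <- expression_matrix(matrix(1:2, 1L, 2L, dimnames = list("Z", c("s1", "s2"))))
  expect_error(align_to_basis(w, bad), "underdetermined")
})

test_that("fixed-basis projection solves the per-column NNLS exactly", {
  w <- gene_program_basis(matrix(c(1, 0, 1, 0, 1, 1), 3L, 2L),
                          gene_ids = c("a", "b", "c"))
  x <- expression_matrix(matrix(c(2, 3, 5, 1, 0, 0, 0, 0, 0), 3L, 3L,
                               dimnames = list(c("a", "b", "c"),
                                               c("interior", "boundary", "zero"))))
  pr <- project_fixed_basis(align_to_basis(w, x))
  h <- pr$activity$values
  expect_equal(unname(h[, "interior"]), c(2, 3), tolerance = 1e-9)
  # unconstrained optimum has a negative coordinate; KKT puts it at zero
  expect_equal(unname(h[, "boundary"]), c(0.5, 0), tolerance = 1e-9)
  expect_equal(unname(h[, "zero"]), c(0, 0))
})

test_that("active-set NNLS agrees with the reference solver on random problems", {
  skip_if_not_installed("pracma")
  for (seed in 1:25) {
    set.seed(seed)
    A <- matrix(rnorm(12L * 4L), 12L, 4L)
    b <- rnorm(12L)
    mine <- progdecon:::nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(mine, ref, tolerance = 1e-8)
    # KKT: gradient nonpositive everywhere, zero on the support
    g <- drop(crossprod(A, b - A %*% mine))
    expect_lt(max(g), 1e-8)
    if (any(mine > 0)) expect_lt(max(abs(g[mine > 0])), 1e-8)
  }
})

test_that("noise-free activities are recovered exactly through the projection", {
  w0 <- simulate_basis(100L, 5L, overlap = 0.3, seed = 0L)
  sim <- simulate_expression(w0, 50L, noise_model = "none", seed = 0L)
  pr <- nmf_project(w0, sim$expression, poh = FALSE)
  rel <- norm(pr$activity$values - sim$activity$values, "F") /
    norm(sim$activity$values, "F")
  expect_lt(rel, 1e-6)
  expect_equal(pr$evar_all, 1, tolerance = 1e-9)
})

test_that("projection evar degrades monotonically with noise on average", {
  w0 <- simulate_basis(80L, 3L, overlap = 0.2, seed = 5L)
  evar_at <- function(noise) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_expression(w0, 25L, noise_model = "gaussian_clipped",
                                 noise_scale = noise, seed = s)
      nmf_project(w0, sim$expression, poh = FALSE)$evar_all
    }, numeric(1L)))
  }
  e <- vapply(c(0.05, 0.3, 1), evar_at, numeric(1L))
  expect_true(all(diff(e) < 0))
})

test_that("projection is equivariant under component and column permutations", {
  w0 <- simulate_basis(60L, 4L, overlap = 0.2, seed = 3L)
  sim <- simulate_expression(w0, 15L, noise_model = "poisson", seed = 3L, depth = 300)
  base <- nmf_project(w0, sim$expression, poh = FALSE)$activity$values
  set.seed(1)
  cp <- sample(4L)
  wp <- gene_program_basis(w0$weights[, cp], gene_ids = w0$gene_ids,
                           component_ids = w0$component_ids[cp])
  permuted <- nmf_project(wp, sim$expression, poh = FALSE)$activity$values
  expect_equal(unname(permuted), unname(base[cp, ]), tolerance = 1e-9)
  jp <- sample(15L)
  xp <- expression_matrix(sim$expression$values[, jp])
  colperm <- nmf_project(w0, xp, poh = FALSE)$activity$values
  expect_equal(unname(colperm), unname(base[, jp]), tolerance = 1e-9)
})

test_that("POH counts overlap fractions with the 0.1 low-quality flag", {
  w <- gene_program_basis(matrix(1, 4L, 1L), gene_ids = c("A", "B", "X", "Y"))
  p <- compute_poh(c("A", "B", "C", "D"), w)
  expect_equal(as.numeric(p), 0.5)
  expect_false(attr(p, "low_quality"))
  expect_equal(as.numeric(compute_poh(c("A", "B"), w)), 1)
  expect_equal(as.numeric(compute_poh(c("Q", "R"), w)), 0)
  p2 <- compute_poh(c("A", rep("Q", 19L)), w)   # 0.05 < 0.1
  expect_equal(as.numeric(p2), 0.05)
  expect_true(attr(p2, "low_quality"))
  p3 <- compute_poh(c("A", rep("Q", 9L)), w)    # exactly 0.1: not low
  expect_false(attr(p3, "low_quality"))
  expect_error(compute_poh(character(0L), w), "domain error")
})

test_that("POH against the fit-time HVG universe uses the stored gene set", {
  w <- gene_program_basis(matrix(1, 2L, 1L), gene_ids = c("A", "B"),
                          hvg_universe = c("A", "B", "C"))
  expect_equal(as.numeric(compute_poh(c("A", "C"), w)), 0.5)
  expect_equal(as.numeric(compute_poh(c("A", "C"), w, use_hvg_universe = TRUE)), 1)
})

test_that("predict on a fitted model projects new data onto the learned basis", {
  w0 <- simulate_basis(80L, 3L, overlap = 0.2, seed = 8L)
  train <- simulate_expression(w0, 60L, noise_model = "none", seed = 8L)
  fit <- fit_nmf(train$expression, 3L, seed = 8L)
  new <- simulate_expression(w0, 10L, noise_model = "none", seed = 9L)
  pr <- predict(fit, new$expression, poh = FALSE)
  expect_s3_class(pr, "nmf_projection")
  expect_gte(pr$evar_all, 0.99)
  expect_identical(colnames(pr$activity$values), new$expression$column_ids)
})
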