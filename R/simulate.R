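#' Simulate a block-structured gene-program basis
#'
#' Generates a nonnegative genes x components basis with known structure:
#' each component owns a contiguous block of `floor(n_genes/k)` dominant
#' genes (leftover genes join the last block), and `overlap` controls how
#' much weight bleeds into other components' blocks (`0` gives disjoint
#' supports, `1` heavy sharing). All draws are seeded, so the same arguments
#' always reproduce the same basis bit-exactly.
#'
#' @param n_genes Number of genes; must be at least `10 * k` so every block
#'   is informative.
#' @param k Number of components.
#' @param overlap Cross-component weight bleed in `[0, 1]`.
#' @param seed Integer seed.
#' @param vdj_fraction Fraction of gene identifiers replaced by V(D)J-segment
#'   decoy symbols (`TRBV...`, `IGHV...`) to exercise the HVG exclusion
#'   filter; default 0.
#' @return A [gene_program_basis()] with gene ids `G000001...`.
#' @export
simulate_basis <- function(n_genes, k, overlap = 0, seed = 0L, vdj_fraction = 0) {
  if (n_genes < 10L * k)
    stop("domain error: n_genes must be >= 10 * k", call. = FALSE)
  if (overlap < 0 || overlap > 1)
    stop("domain error: overlap must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    b <- n_genes %/% k
    w <- matrix(overlap * stats::runif(n_genes * k, 0, 0.3), n_genes, k)
    for (c in seq_len(k)) {
      rows <- if (c < k) ((c - 1L) * b + 1L):(c * b) else ((c - 1L) * b + 1L):n_genes
      w[rows, c] <- stats::runif(length(rows), 0.5, 2)
    }
    ids <- sprintf("G%06d", seq_len(n_genes))
    if (vdj_fraction > 0) {
      n_vdj <- floor(vdj_fraction * n_genes)
      pick <- sample.int(n_genes, n_vdj)
      pref <- sample(c("TRBV", "TRAV", "IGHV", "IGKV"), n_vdj, replace = TRUE)
      ids[pick] <- sprintf("%s%03d", pref, seq_len(n_vdj))
    }
    gene_program_basis(w, gene_ids = ids)
  })
}

#' Simulate expression from a known basis
#'
#' Draws nonnegative per-column activities `H` i.i.d. from a right-skewed
#' gamma (shape 2 by default, so programs are occasionally near-silent) and
#' builds `X = W %*% H` plus noise. Noise models: `"none"` (exact product),
#' `"gaussian_clipped"` (additive normal with sd `noise_scale`, clipped at
#' zero — convenient for analytic-style tests) and `"poisson"` (counts with
#' mean `W %*% H`, the single-cell-like default).
#'
#' @param w_true A [gene_program_basis()] (e.g. from [simulate_basis()]).
#' @param n_columns Number of columns (cells/samples) to draw; must be >= 1.
#' @param noise_model One of `"poisson"`, `"gaussian_clipped"`, `"none"`.
#' @param noise_scale Noise sd for `"gaussian_clipped"`; ignored otherwise.
#' @param seed Integer seed.
#' @param depth If given, each noise-free column of `W %*% H` is rescaled to
#'   this total before noise, emulating a target sequencing depth.
#' @param activity_shape,activity_scale Gamma parameters for the activities.
#' @return List with `expression` ([expression_matrix()]), `activity` (the
#'   true [program_activity()]), and `truth` (class `simulation_truth`:
#'   generator arguments and the true factors).
#' @export
simulate_expression <- function(w_true, n_columns,
                                noise_model = c("poisson", "gaussian_clipped", "none"),
                                noise_scale = 0, seed = 0L, depth = NULL,
                                activity_shape = 2, activity_scale = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(w_true, "gene_program_basis"))
  if (!is.numeric(n_columns) || n_columns < 1L)
    stop("domain error: n_columns must be >= 1", call. = FALSE)
  if (noise_scale < 0)
    stop("domain error: noise_scale must be >= 0", call. = FALSE)
  k <- ncol(w_true$weights)
  with_seed(seed, {
    h <- matrix(stats::rgamma(k * n_columns, shape = activity_shape,
                              scale = activity_scale), k, n_columns)
    m <- w_true$weights %*% h
    if (!is.null(depth)) {
      cs <- colSums(m)
      scale_by <- ifelse(cs > 0, depth / cs, 1)
      m <- sweep(m, 2L, scale_by, "*")
      h <- sweep(h, 2L, scale_by, "*")
    }
    x <- switch(noise_model,
      none = m,
      gaussian_clipped = pmax(m + matrix(stats::rnorm(length(m), 0, noise_scale),
                                         nrow(m), ncol(m)), 0),
      poisson = matrix(stats::rpois(length(m), m), nrow(m), ncol(m)))
    col_ids <- sprintf("C%06d", seq_len(n_columns))
    expr <- expression_matrix(x, gene_ids = w_true$gene_ids,
                              column_ids = col_ids,
                              value_kind = if (noise_model == "poisson") "raw_count" else "other")
    act <- program_activity(h, component_ids = w_true$component_ids,
                            column_ids = col_ids)
    truth <- structure(list(true_basis = w_true, true_activity = act,
                            noise_model = noise_model, noise_scale = noise_scale,
                            depth = depth, seed = seed),
                       class = "simulation_truth")
    list(expression = expr, activity = act, truth = truth)
  })
}

# Per-sample design indicators for the declared effect names.
cohort_effect_names <- function(diseases, projects) {
  c(paste0("disease_", setdiff(diseases, "healthy")),
    "age_per_25y", "gender_female",
    paste0("project_", projects[-1L]))
}

#' Simulate a multi-project cohort with planted effects
#'
#' Generates per-sample metadata (disease drawn uniformly over the declared
#' levels, age uniform over `age_range`, balanced gender, uniform project),
#' then per focal cluster computes the cluster probability through the logit
#' model `qlogis(baseline_prob) + declared effects`, draws `n_cat` from the
#' binomial, and assigns the remaining cells to an `"other"` cluster so the
#' per-sample counts always sum to `cells_per_sample`. Optional program
#' features are drawn from the linear model
#' `feature_baseline + declared effects + N(0, residual_sd)`.
#'
#' Effect names must be among `disease_<level>` (log-odds / feature units vs
#' healthy), `age_per_25y` (per 25 years), `gender_female`, and
#' `project_<id>`; anything else is an error. `mean_xist` is generated
#' concordant with gender (female high, male near zero) so sex QC passes by
#' default.
#'
#' @param n_samples Number of samples.
#' @param diseases Disease levels, must include `"healthy"`.
#' @param effects Named numeric vector/list of log-odds effects on the
#'   cluster-frequency logit (applied to every focal cluster).
#' @param cells_per_sample Total cells per sample (`n_total`).
#' @param seed Integer seed.
#' @param clusters Focal cluster names; default `"C1"`.
#' @param baseline_prob Baseline (healthy, male, age 0, reference project)
#'   cluster probability per focal cluster, recycled; default 0.1.
#' @param feature_components Component labels to simulate features for
#'   (empty for none).
#' @param feature_effects Named effects on the feature linear predictor.
#' @param feature_baseline Baseline feature value; default 1.
#' @param residual_sd Feature residual sd; default 0.3.
#' @param n_projects Number of projects; default 2.
#' @param age_range Uniform age range in years; default `c(20, 80)`.
#' @return List with `cohort` (a [cohort_table()]) and `truth` (class
#'   `simulation_truth` carrying the declared coefficients and seed).
#' @export
simulate_cohort <- function(n_samples, diseases = c("healthy", "disease"),
                            effects = c(disease_disease = 0),
                            cells_per_sample = 1000L, seed = 0L,
                            clusters = "C1", baseline_prob = 0.1,
                            feature_components = character(0L),
                            feature_effects = c(), feature_baseline = 1,
                            residual_sd = 0.3, n_projects = 2L,
                            age_range = c(20, 80)) {
  if (!"healthy" %in% diseases)
    stop("domain error: diseases must include 'healthy'", call. = FALSE)
  projects <- paste0("P", seq_len(n_projects))
  allowed <- cohort_effect_names(diseases, projects)
  effects <- unlist(effects)
  feature_effects <- unlist(feature_effects)
  bad <- setdiff(c(names(effects), names(feature_effects)), allowed)
  if (length(bad))
    stop("domain error: unknown effect term(s): ", paste(bad, collapse = ", "),
         "; declared terms are ", paste(allowed, collapse = ", "), call. = FALSE)
  baseline_prob <- rep_len(baseline_prob, length(clusters))
  if (any(baseline_prob <= 0 | baseline_prob >= 1))
    stop("domain error: baseline_prob must lie in (0, 1)", call. = FALSE)

  with_seed(seed, {
    meta <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n_samples)),
      disease = sample(diseases, n_samples, replace = TRUE),
      age = stats::runif(n_samples, age_range[1L], age_range[2L]),
      gender = sample(c("male", "female"), n_samples, replace = TRUE),
      project = sample(projects, n_samples, replace = TRUE),
      stringsAsFactors = FALSE)
    meta$mean_xist <- ifelse(meta$gender == "female",
                             stats::runif(n_samples, 0.2, 1),
                             stats::runif(n_samples, 0, 0.02))

    design <- matrix(0, n_samples, length(allowed),
                     dimnames = list(meta$sample_id, allowed))
    for (lev in setdiff(diseases, "healthy"))
      design[, paste0("disease_", lev)] <- as.numeric(meta$disease == lev)
    design[, "age_per_25y"] <- meta$age / 25
    design[, "gender_female"] <- as.numeric(meta$gender == "female")
    for (pr in projects[-1L])
      design[, paste0("project_", pr)] <- as.numeric(meta$project == pr)
    lp <- function(coefs) {
      if (length(coefs) == 0L) return(numeric(n_samples))
      drop(design[, names(coefs), drop = FALSE] %*% coefs)
    }

    eta_effects <- lp(effects)
    counts <- matrix(0L, n_samples, length(clusters) + 1L,
                     dimnames = list(meta$sample_id, c(clusters, "other")))
    for (ci in seq_along(clusters)) {
      p <- stats::plogis(stats::qlogis(baseline_prob[ci]) + eta_effects)
      counts[, ci] <- stats::rbinom(n_samples, cells_per_sample, p)
    }
    other <- cells_per_sample - rowSums(counts[, seq_along(clusters), drop = FALSE])
    if (any(other < 0))
      stop("domain error: focal cluster draws exceed cells_per_sample for sample(s) ",
           paste(meta$sample_id[other < 0], collapse = ", "),
           "; lower baseline_prob or effects", call. = FALSE)
    counts[, "other"] <- other

    features <- NULL
    if (length(feature_components)) {
      eta_feat <- feature_baseline + lp(feature_effects)
      features <- do.call(rbind, lapply(clusters, function(cl) {
        do.call(rbind, lapply(feature_components, function(cp) {
          data.frame(sample_id = meta$sample_id, cluster = cl, component = cp,
                     value = eta_feat + stats::rnorm(n_samples, 0, residual_sd),
                     stringsAsFactors = FALSE)
        }))
      }))
    }

    truth <- structure(list(cohort_effects = effects,
                            feature_effects = feature_effects,
                            baseline_prob = stats::setNames(baseline_prob, clusters),
                            feature_baseline = feature_baseline,
                            residual_sd = residual_sd, seed = seed),
                       class = "simulation_truth")
    list(cohort = cohort_table(meta, counts, features), truth = truth)
  })
}
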