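#' Assemble a cohort table
#'
#' Per-sample metadata, per-cluster cell counts, and (optionally) per-cluster
#' program-activity means, as used by the cohort-level GLMs: a binomial GLM
#' on `(n_cat, n_total - n_cat)` for cell-frequency change and a linear GLM
#' on per-sample program means for activity change.
#'
#' @param meta Data frame with columns `sample_id`, `disease` (must contain
#'   the level `"healthy"`), `age` (years), `gender` (`"male"`/`"female"`),
#'   `project`; optionally `mean_xist` (mean raw count of the XIST gene,
#'   used by [infer_sex_qc()]).
#' @param counts Integer matrix, samples x clusters, of cells per cluster
#'   (`n_cat`); rownames are sample ids. `n_total` is its row sum.
#' @param features Optional long data frame `sample_id`, `cluster`,
#'   `component`, `value` of per-sample mean program activities.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(meta, counts, features = NULL) {
  req <- c("sample_id", "disease", "age", "gender", "project")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("format error: metadata lacks column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("format error: duplicate sample_id in metadata", call. = FALSE)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- meta$sample_id
  if (!setequal(rownames(counts), meta$sample_id))
    stop("format error: count matrix samples do not match metadata", call. = FALSE)
  counts <- counts[meta$sample_id, , drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("domain error: cell counts must be nonnegative integers", call. = FALSE)
  if (!"healthy" %in% meta$disease)
    stop("format error: disease column must contain the baseline level 'healthy'",
         call. = FALSE)
  if (!is.null(features)) {
    freq <- c("sample_id", "cluster", "component", "value")
    if (!all(freq %in% names(features)))
      stop("format error: features needs columns ", paste(freq, collapse = ", "),
           call. = FALSE)
    features$sample_id <- as.character(features$sample_id)
  }
  structure(list(meta = meta, counts = counts,
                 n_total = rowSums(counts), features = features),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d samples, %d clusters, diseases: %s\n",
              nrow(x$meta), ncol(x$counts),
              paste(sort(unique(x$meta$disease)), collapse = ", ")))
  if (!is.null(x$features))
    cat(sprintf("  features: %d components\n", length(unique(x$features$component))))
  invisible(x)
}

#' Sex-concordance sample QC from XIST expression
#'
#' A sample is inferred female when its mean raw XIST count exceeds the
#' threshold (default 0.05). Samples whose inferred sex contradicts the
#' recorded gender are flagged for removal; samples without a `mean_xist`
#' value pass with a notice.
#'
#' @param cohort A [cohort_table()] (or a metadata data frame with
#'   `sample_id`, `gender`, `mean_xist`).
#' @param threshold Mean-count cutoff; default 0.05.
#' @return Data frame `sample_id`, `mean_xist`, `inferred_gender`,
#'   `recorded_gender`, `flagged`.
#' @export
infer_sex_qc <- function(cohort, threshold = 0.05) {
  meta <- if (inherits(cohort, "cohort_table")) cohort$meta else cohort
  if (is.null(meta$mean_xist)) {
    message("no mean_xist column; all samples pass sex QC unchecked")
    return(data.frame(sample_id = meta$sample_id, mean_xist = NA_real_,
                      inferred_gender = NA_character_,
                      recorded_gender = as.character(meta$gender),
                      flagged = FALSE, stringsAsFactors = FALSE))
  }
  checked <- !is.na(meta$mean_xist)
  inferred <- ifelse(meta$mean_xist > threshold, "female", "male")
  inferred[!checked] <- NA_character_
  flagged <- checked & inferred != as.character(meta$gender)
  if (any(!checked))
    message(sum(!checked), " sample(s) lack mean_xist; passed unchecked")
  data.frame(sample_id = meta$sample_id, mean_xist = meta$mean_xist,
             inferred_gender = inferred,
             recorded_gender = as.character(meta$gender),
             flagged = flagged, stringsAsFactors = FALSE)
}

# Design frame shared by the frequency and feature models: disease releveled
# to healthy, gender to male, project to its first-observed level, age/25.
# Single-level factors are dropped with a warning. Returns the frame plus the
# retained right-hand-side terms.
cohort_design <- function(meta) {
  df <- data.frame(row.names = meta$sample_id)
  rhs <- character(0L)
  disease <- factor(meta$disease)
  if (nlevels(disease) >= 2L) {
    df$disease <- stats::relevel(disease, ref = "healthy")
    rhs <- c(rhs, "disease")
  } else {
    warning("disease has a single level; disease terms dropped", call. = FALSE)
  }
  df$age_per_25y <- meta$age / 25
  rhs <- c(rhs, "age_per_25y")
  gender <- factor(meta$gender, levels = c("male", "female"))
  gender <- droplevels(gender)
  if (nlevels(gender) >= 2L) {
    df$gender <- gender
    rhs <- c(rhs, "gender")
  } else {
    warning("gender has a single level; gender term dropped", call. = FALSE)
  }
  project <- factor(meta$project, levels = unique(as.character(meta$project)))
  if (nlevels(project) >= 2L) {
    df$project <- project
    rhs <- c(rhs, "project")
  } else {
    warning("project has a single level; project term dropped", call. = FALSE)
  }
  list(frame = df, rhs = rhs)
}

# Pretty term labels: factor terms become var_level; intercept and the
# scaled-age slope keep their own names.
pretty_terms <- function(terms, frame) {
  out <- terms
  out[out == "(Intercept)"] <- "intercept"
  for (v in names(frame)) {
    if (!is.factor(frame[[v]])) next
    for (lev in levels(frame[[v]])) {
      out[out == paste0(v, lev)] <- paste0(v, "_", lev)
    }
  }
  out
}

glm_to_estimates <- function(fit, frame, cluster, component = NA_character_) {
  sm <- summary(fit)$coefficients
  notes <- rep("", nrow(sm))
  if (any(sm[, "Std. Error"] > 100) || any(abs(sm[, "Estimate"]) > 15)) {
    sep <- sm[, "Std. Error"] > 100 | abs(sm[, "Estimate"]) > 15
    notes[sep] <- "possible separation: unstable estimate"
    warning("cluster ", cluster, ": possible separation for term(s) ",
            paste(rownames(sm)[sep], collapse = ", "), call. = FALSE)
  }
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    warning("cluster ", cluster, ": aliased term(s) dropped: ",
            paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
  data.frame(cluster = cluster, component = component,
             term = pretty_terms(rownames(sm), frame),
             coefficient = sm[, "Estimate"], std_error = sm[, "Std. Error"],
             p_value = sm[, ncol(sm)], q_value = NA_real_, note = notes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cluster binomial GLM for cell-frequency change
#'
#' Models the frequency of one cell cluster across a cohort: a binomial GLM
#' with logit link on the response `(n_cat, n_total - n_cat)` with linear
#' predictor `disease + age/25 + gender + project`. Disease is one-hot with
#' `healthy` as baseline; age is divided by 25 to put its coefficient on the
#' scale of the categorical terms; gender reference is `male`; project
#' reference is its first-observed level. Coefficients are log-odds; p-values
#' are Wald. q-values are left `NA` — the multiplicity family spans clusters,
#' so adjust with [cohort_frequency_scan()] or [adjust_fdr()].
#'
#' @param cohort A [cohort_table()].
#' @param cluster Cluster (column of the count matrix) to model.
#' @param apply_sex_qc Remove samples failing [infer_sex_qc()] first (only
#'   when `mean_xist` is available); default `TRUE`.
#' @return Data frame of class `effect_estimates`: `cluster`, `component`
#'   (`NA`), `term`, `coefficient`, `std_error`, `p_value`, `q_value`,
#'   `note`.
#' @export
fit_frequency_model <- function(cohort, cluster, apply_sex_qc = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!cluster %in% colnames(cohort$counts))
    stop("domain error: unknown cluster '", cluster, "'", call. = FALSE)
  meta <- cohort$meta
  n_cat <- cohort$counts[, cluster]
  n_total <- cohort$n_total
  keep <- n_total > 0
  if (apply_sex_qc && !is.null(meta$mean_xist))
    keep <- keep & !infer_sex_qc(cohort)$flagged
  meta <- meta[keep, , drop = FALSE]
  n_cat <- n_cat[keep]
  n_total <- n_total[keep]
  des <- cohort_design(meta)
  df <- des$frame
  df$n_cat <- n_cat
  df$n_fail <- n_total - n_cat
  fml <- stats::as.formula(paste("cbind(n_cat, n_fail) ~",
                                 paste(des$rhs, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  out <- glm_to_estimates(fit, des$frame, cluster)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Per-cluster, per-component linear GLM for program-activity change
#'
#' Ordinary least squares of the per-sample mean activity of one program
#' component within one cluster on `disease + age/25 + gender + project`,
#' with the same encodings and baselines as [fit_frequency_model()]. The
#' intercept (baseline activity in healthy male samples at age 0 on the
#' scaled axis) is reported and feeds [scale_intercepts()].
#'
#' @inheritParams fit_frequency_model
#' @param component Program component label to model.
#' @return Data frame of class `effect_estimates` (see
#'   [fit_frequency_model()]) with the `component` column filled.
#' @export
fit_feature_model <- function(cohort, cluster, component, apply_sex_qc = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(cohort$features))
    stop("domain error: cohort has no feature table", call. = FALSE)
  feat <- cohort$features
  feat <- feat[feat$cluster == cluster & feat$component == component, , drop = FALSE]
  if (nrow(feat) == 0L)
    stop("domain error: no feature values for cluster '", cluster,
         "', component '", component, "'", call. = FALSE)
  meta <- cohort$meta
  if (apply_sex_qc && !is.null(meta$mean_xist))
    meta <- meta[!infer_sex_qc(cohort)$flagged, , drop = FALSE]
  idx <- match(meta$sample_id, feat$sample_id)
  keep <- !is.na(idx)
  meta <- meta[keep, , drop = FALSE]
  value <- feat$value[idx[keep]]
  des <- cohort_design(meta)
  df <- des$frame
  df$value <- value
  fml <- stats::as.formula(paste("value ~", paste(des$rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  out <- glm_to_estimates(fit, des$frame, cluster, component = component)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up: sorted `p * n / rank` with enforced monotonicity,
#' capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Fit the frequency model for every cluster and adjust FDR
#'
#' Runs [fit_frequency_model()] per cluster and applies BH adjustment across
#' clusters within each term (the multiplicity family is "one hypothesis per
#' cluster for a given condition").
#'
#' @inheritParams fit_frequency_model
#' @param clusters Clusters to fit; default all columns of the count matrix.
#' @return Combined `effect_estimates` data frame with `q_value` filled;
#'   attribute `fdr_family = "term"`.
#' @export
cohort_frequency_scan <- function(cohort, clusters = colnames(cohort$counts),
                                  apply_sex_qc = TRUE) {
  res <- do.call(rbind, lapply(clusters, function(cl)
    fit_frequency_model(cohort, cl, apply_sex_qc = apply_sex_qc)))
  for (tm in unique(res$term))
    res$q_value[res$term == tm] <- adjust_fdr(res$p_value[res$term == tm])
  attr(res, "fdr_family") <- "term"
  res
}

#' Fit the feature model for every (cluster, component) and adjust FDR
#'
#' Runs [fit_feature_model()] over all cluster/component combinations in the
#' feature table and applies BH adjustment across clusters within each
#' (term, component) pair.
#'
#' @inheritParams fit_frequency_model
#' @return Combined `effect_estimates` data frame with `q_value` filled;
#'   attribute `fdr_family = "term-component"`.
#' @export
cohort_feature_scan <- function(cohort, apply_sex_qc = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"), !is.null(cohort$features))
  combos <- unique(cohort$features[, c("cluster", "component")])
  res <- do.call(rbind, Map(function(cl, cp)
    fit_feature_model(cohort, cl, cp, apply_sex_qc = apply_sex_qc),
    combos$cluster, combos$component))
  for (tm in unique(res$term)) {
    for (cp in unique(res$component)) {
      sel <- res$term == tm & res$component == cp
      res$q_value[sel] <- adjust_fdr(res$p_value[sel])
    }
  }
  attr(res, "fdr_family") <- "term-component"
  res
}

#' Min-max scale baseline intercepts across clusters
#'
#' For each program component, the fitted intercepts (baseline program
#' activity) are min-max scaled to `[0, 1]` across clusters, giving a
#' comparable "which cluster carries this program at baseline" score. Raw
#' intercepts are retained alongside. With a single cluster, or when all
#' intercepts are equal, the scaled value is defined as 0 with a warning.
#'
#' @param estimates An `effect_estimates` data frame containing
#'   `term == "intercept"` rows for one or more components across clusters
#'   (e.g. from [cohort_feature_scan()]).
#' @return Data frame `component`, `cluster`, `intercept`,
#'   `scaled_intercept`.
#' @export
scale_intercepts <- function(estimates) {
  ic <- estimates[estimates$term == "intercept" & !is.na(estimates$component), ,
                  drop = FALSE]
  if (nrow(ic) == 0L)
    stop("domain error: no component intercepts found", call. = FALSE)
  out <- do.call(rbind, lapply(split(ic, ic$component), function(g) {
    rng <- range(g$coefficient)
    if (nrow(g) < 2L || rng[1L] == rng[2L]) {
      warning("component ", g$component[1L],
              ": degenerate intercept range; scaled values set to 0",
              call. = FALSE)
      scaled <- rep(0, nrow(g))
    } else {
      scaled <- (g$coefficient - rng[1L]) / (rng[2L] - rng[1L])
    }
    data.frame(component = g$component, cluster = g$cluster,
               intercept = g$coefficient, scaled_intercept = scaled,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
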