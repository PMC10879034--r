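make_cohort <- function(n = 60L, seed = 1L, effects = c(disease_ra = 0), ...) {
  simulate_cohort(n, diseases = c("healthy", "ra"), effects = effects,
                  seed = seed, ...)
}

test_that("cohort assembly enforces count conservation and required columns", {
  sim <- make_cohort(effects = c(disease_ra = 0.3))
  co <- sim$cohort
  expect_identical(unname(rowSums(co$counts)), unname(co$n_total))
  expect_true(all(co$counts <= co$n_total))
  meta_bad <- co$meta
  meta_bad$disease <- "ra"   # no healthy baseline
  expect_error(cohort_table(meta_bad, co$counts), "healthy")
  expect_error(cohort_table(co$meta[, -2L], co$counts), "format error")
})

test_that("sex inference flags metadata discordance at the XIST threshold", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     disease = "healthy", age = 40, project = "P1",
                     gender = c("female", "male", "male", "female"),
                     mean_xist = c(0.10, 0.10, 0.0, NA),
                     stringsAsFactors = FALSE)
  qc <- suppressMessages(infer_sex_qc(meta))
  expect_identical(qc$flagged, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(qc$inferred_gender[1:3], c("female", "female", "male"))
  # threshold is strict: exactly 0.05 infers male
  meta$mean_xist <- 0.05
  qc2 <- infer_sex_qc(meta)
  expect_identical(qc2$inferred_gender, rep("male", 4L))
})

test_that("flagged samples are removed before model fitting", {
  sim <- make_cohort(n = 80L, effects = c(disease_ra = 0))
  co <- sim$cohort
  co$meta$mean_xist[co$meta$gender == "male"][1:3] <- 0.5  # 3 discordant males
  fit_all <- fit_frequency_model(co, "C1", apply_sex_qc = FALSE)
  fit_qc <- fit_frequency_model(co, "C1", apply_sex_qc = TRUE)
  expect_false(isTRUE(all.equal(fit_all$coefficient, fit_qc$coefficient)))
})

test_that("frequency model recovers a planted disease log-odds effect", {
  est <- se <- numeric(25L)
  for (s in seq_len(25L)) {
    sim <- simulate_cohort(400L, c("healthy", "disease"),
                           c(disease_disease = 0.7), cells_per_sample = 1000L,
                           seed = s, baseline_prob = 0.1)
    row <- fit_frequency_model(sim$cohort, "C1")
    est[s] <- row$coefficient[row$term == "disease_disease"]
    se[s] <- row$std_error[row$term == "disease_disease"]
  }
  expect_lt(abs(mean(est) - 0.7), 0.05)
  expect_true(all(abs(est - 0.7) < 6 * se))
})

test_that("model encoding uses healthy/male/first-project references and age/25", {
  sim <- simulate_cohort(120L, c("healthy", "ra", "sle"),
                         c(disease_ra = 0.4, disease_sle = -0.2),
                         seed = 5L, n_projects = 3L)
  res <- fit_frequency_model(sim$cohort, "C1")
  ref_project <- sim$cohort$meta$project[1L]   # first-observed is the reference
  other_projects <- setdiff(paste0("P", 1:3), ref_project)
  expect_setequal(
    res$term,
    c("intercept", "disease_ra", "disease_sle", "age_per_25y",
      "gender_female", paste0("project_", other_projects)))
  # age scaling: refit with age in design units to cross-check the slope
  co2 <- sim$cohort
  co2$meta$age <- co2$meta$age * 2
  res2 <- fit_frequency_model(co2, "C1")
  expect_equal(res2$coefficient[res2$term == "age_per_25y"],
               res$coefficient[res$term == "age_per_25y"] / 2,
               tolerance = 1e-8)
})

test_that("reordering disease levels leaves estimates identical up to labels", {
  sim <- simulate_cohort(150L, c("healthy", "ra", "sle"),
                         c(disease_ra = 0.5, disease_sle = 0.2), seed = 9L)
  co <- sim$cohort
  res1 <- fit_frequency_model(co, "C1")
  co2 <- co
  perm <- order(match(co2$meta$disease, c("sle", "ra", "healthy")))
  co2$meta <- co2$meta[perm, , drop = FALSE]
  co2$counts <- co2$counts[perm, , drop = FALSE]
  co2$n_total <- co2$n_total[perm]
  res2 <- fit_frequency_model(co2, "C1")
  m <- match(res1$term, res2$term)
  expect_equal(res1$coefficient, res2$coefficient[m], tolerance = 1e-10)
})

test_that("single-level terms are dropped with a warning, not an error", {
  sim <- make_cohort(n = 40L, effects = c(disease_ra = 0))
  co <- sim$cohort
  co$meta$disease <- "healthy"
  expect_warning(res <- fit_frequency_model(co, "C1"), "single level")
  expect_false(any(grepl("^disease", res$term)))
  expect_true("age_per_25y" %in% res$term)
})

test_that("feature model recovers effects, scales age and handles constants", {
  est <- numeric(25L)
  for (s in seq_len(25L)) {
    sim <- simulate_cohort(300L, c("healthy", "disease"), c(disease_disease = 0),
                           seed = 100L + s, feature_components = "NMF0",
                           feature_effects = c(disease_disease = 0.5),
                           residual_sd = 0.3)
    fm <- fit_feature_model(sim$cohort, "C1", "NMF0")
    est[s] <- fm$coefficient[fm$term == "disease_disease"]
  }
  expect_lt(abs(mean(est) - 0.5), 0.05)

  sim <- make_cohort(feature_components = "NMF1", residual_sd = 0)
  co <- sim$cohort
  co$features$value <- 2.5
  fm <- suppressWarnings(fit_feature_model(co, "C1", "NMF1"))  # perfect fit
  expect_equal(fm$coefficient[fm$term == "intercept"], 2.5, tolerance = 1e-10)
  slopes <- fm$coefficient[fm$term != "intercept"]
  expect_true(all(abs(slopes) < 1e-10))
})

test_that("BH adjustment matches hand-worked cases and respects bounds", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  expect_error(adjust_fdr(c(0.5, 1.2)), "domain error")
  p <- c(0.04, 0.001, 0.7)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
})

test_that("BH adjustment equals the brute-force oracle on random vectors", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(1:1000, 1L)
    p <- runif(n)
    expect_lt(max(abs(adjust_fdr(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("scan wrappers fill q-values within the declared family", {
  sim <- simulate_cohort(200L, c("healthy", "ra"), c(disease_ra = 0.5),
                         seed = 21L, clusters = c("C1", "C2", "C3"),
                         baseline_prob = c(0.1, 0.15, 0.2),
                         feature_components = c("NMF0", "NMF1"),
                         feature_effects = c(disease_ra = 0.4))
  fr <- cohort_frequency_scan(sim$cohort)
  expect_false(anyNA(fr$q_value))
  for (tm in unique(fr$term)) {
    sel <- fr$term == tm
    expect_equal(fr$q_value[sel], adjust_fdr(fr$p_value[sel]))
  }
  fe <- cohort_feature_scan(sim$cohort)
  sel <- fe$term == "disease_ra" & fe$component == "NMF0"
  expect_identical(sum(sel), 3L)   # one per cluster
  expect_equal(fe$q_value[sel], adjust_fdr(fe$p_value[sel]))
})

test_that("intercepts are min-max scaled per component across clusters", {
  est <- data.frame(cluster = c("T1", "T2", "T3", "T1", "T2"),
                    component = c("NMF0", "NMF0", "NMF0", "NMF1", "NMF1"),
                    term = "intercept",
                    coefficient = c(0.2, 0.6, 1.0, -0.1, 0.1),
                    stringsAsFactors = FALSE)
  sc <- scale_intercepts(est)
  expect_equal(sc$scaled_intercept[sc$component == "NMF0"], c(0, 0.5, 1))
  expect_equal(sc$scaled_intercept[sc$component == "NMF1"], c(0, 1))
  expect_equal(sc$intercept, est$coefficient)   # raw values retained
  flat <- est[1:3, ]
  flat$coefficient <- 0.4
  expect_warning(sc2 <- scale_intercepts(flat), "degenerate")
  expect_equal(sc2$scaled_intercept, rep(0, 3L))
  single <- est[1L, ]
  expect_warning(sc3 <- scale_intercepts(single), "degenerate")
  expect_equal(sc3$scaled_intercept, 0)
})
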