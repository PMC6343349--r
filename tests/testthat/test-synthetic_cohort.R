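test_that("default parameters encode the published population structure", {
  p <- default_params("dementia")
  expect_equal(p$n_cases + p$n_controls, 245)
  expect_equal(p$n_cases, 97)
  mm <- p$variables$mmse_total
  expect_equal(mm$mean, c(25.3, 22.2))  # (control, case)
  expect_equal(unname(p$missing_counts[c("education", "apoe_genotype")]),
               c(3L, 3L))
  pp <- default_params("pathology")
  expect_equal(pp$n_cases + pp$n_controls, 163)
  expect_equal(unname(pp$pathology$prevalence[["amyloid"]]), 126 / 163)
})

test_that("generation is deterministic with exact class counts", {
  p <- default_params("dementia")
  c1 <- generate_cohort(p, seed = 17)
  c2 <- generate_cohort(p, seed = 17)
  expect_identical(c1, c2)
  c3 <- generate_cohort(p, seed = 18)
  expect_false(identical(c1$mmse_total, c3$mmse_total))
  expect_equal(sum(c1$outcome == 1, na.rm = TRUE), 97)
  expect_equal(sum(c1$outcome == 0, na.rm = TRUE), 148)
  expect_equal(nrow(c1), 339)
  expect_equal(sum(c1$died_within_2y), 94)
})

test_that("generated tables pass cohort validation with zero warnings", {
  p <- default_params("dementia")
  co <- generate_cohort(p, seed = 23)
  expect_no_warning(v <- validate_cohort(co, attr(co, "specs")))
  expect_true(v$ok)
  # APOE carrier consistency holds row-wise
  g <- co$apoe_genotype
  ok <- !is.na(g)
  expect_equal(co$apoe_e2_carrier[ok], as.numeric(grepl("e2", g[ok])))
  expect_equal(co$apoe_e4_carrier[ok], as.numeric(grepl("e4", g[ok])))
  expect_equal(co$apoe_e3e3[ok], as.numeric(g[ok] == "e3e3"))
  # a carrier of either allele is never the e3e3 homozygote
  carrier <- co$apoe_e2_carrier[ok] + co$apoe_e4_carrier[ok] >= 1
  expect_true(all(g[ok][carrier] != "e3e3"))
})

test_that("per-group sample means approach their targets as n grows", {
  p <- default_params("dementia")
  p$n_cases <- 970L
  p$n_controls <- 1480L
  p$n_died_within_2y <- 0L
  p$missing_counts <- integer()
  co <- generate_cohort(p, seed = 29)
  for (v in c("education", "bmi", "total_cholesterol", "systolic_bp",
              "zung_depression", "age")) {
    par <- p$variables[[v]]
    for (grp in 1:2) {
      # grp 1 = control (outcome 0), grp 2 = case (outcome 1)
      vals <- co[[v]][!is.na(co$outcome) & co$outcome == (grp - 1L)]
      target <- par$mean[grp]
      se <- par$sd[grp] / sqrt(length(vals))
      expect_lt(abs(mean(vals) - target), 3 * se,
                label = sprintf("%s group %d mean |%.3f - %.3f|", v, grp,
                                mean(vals), target))
    }
  }
})

test_that("missing-data injection is exact, seeded, and spares the outcome", {
  p <- default_params("dementia")
  co <- generate_cohort(p, seed = 31, inject = FALSE)
  expect_equal(sum(is.na(co$education)), 0)
  m1 <- inject_missing(co, c(education = 3L, mmse_total = 5L), seed = 7)
  expect_equal(sum(is.na(m1$education)), 3)
  expect_equal(sum(is.na(m1$mmse_total)), 5)
  m2 <- inject_missing(co, c(education = 3L, mmse_total = 5L), seed = 7)
  expect_identical(which(is.na(m2$education)), which(is.na(m1$education)))
  m0 <- inject_missing(co, c(education = 0L), seed = 7)
  expect_identical(m0$education, co$education)
  expect_error(inject_missing(co, c(education = nrow(co) + 1L), seed = 1),
               "exceeds")
  expect_error(inject_missing(co, c(outcome = 1L), seed = 1), "never masked")
  expect_error(inject_missing(co, c(nope = 1L), seed = 1), "not in cohort")
})

test_that("a Gaussian copula induces the requested rank correlation", {
  p <- null_params(n_cases = 400L, n_controls = 400L, n_factors = 2L)
  R <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("f01", "f02"),
                                                    c("f01", "f02")))
  p$copula <- R
  co <- generate_cohort(p, seed = 37)
  expect_gt(cor(co$f01, co$f02, method = "spearman"), 0.6)
  p$copula <- NULL
  co0 <- generate_cohort(p, seed = 37)
  expect_lt(abs(cor(co0$f01, co0$f02)), 0.15)
})

test_that("pathology panel prevalences track their targets", {
  p <- default_params("pathology")
  sim <- generate_pathology_panel(p, seed = 41)
  expect_equal(nrow(sim$panel), 163)
  expect_equal(nrow(sim$cohort), 163)
  d <- derive_outcomes(sim$panel)
  prev <- p$pathology$prevalence
  # binomial tolerance: 3 sd at n = 163
  tol3 <- function(pr) 3 * sqrt(pr * (1 - pr) / 163)
  for (oc in c("amyloid", "tangles", "neuropath_ad", "caa",
               "macroinfarcts", "microinfarcts", "alpha_synuclein",
               "hs", "tdp43")) {
    obs <- mean(d[[paste0("outcome_", oc)]], na.rm = TRUE)
    expect_lt(abs(obs - prev[[oc]]), tol3(prev[[oc]]) + 0.02, label = oc)
  }
  # quantitative magnitudes are zero exactly when pathology is absent
  expect_true(all((sim$panel$amyloid_load > 0) == (d$outcome_amyloid == 1),
                  na.rm = TRUE))
  # zero-prevalence outcome is uniformly absent
  p0 <- p
  p0$pathology$prevalence[["hs"]] <- 0
  sim0 <- generate_pathology_panel(p0, seed = 41)
  expect_true(all(sim0$panel$hs_severity == "no_minor", na.rm = TRUE))
  expect_error({
    pbad <- p
    pbad$pathology$prevalence[["hs"]] <- 1.4
    generate_pathology_panel(pbad, seed = 1)
  }, "prevalences")
})

test_that("planted AD-trio co-occurrence surfaces on PC1", {
  p <- default_params("pathology")
  sim <- generate_pathology_panel(p, seed = 47)
  d <- derive_outcomes(sim$panel)
  mat <- d[, c("amyloid_load", "tangle_count", "caa_percent",
               "macroinfarct_count", "microinfarct_count",
               "outcome_alpha_synuclein", "outcome_hs", "outcome_tdp43")]
  pca <- run_pca(mat)
  top3 <- names(sort(abs(pca$loadings[, 1]), decreasing = TRUE))[1:3]
  expect_setequal(top3, c("amyloid_load", "tangle_count", "caa_percent"))
})
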