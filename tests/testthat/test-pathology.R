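test_that("NIA-AA likelihood lookup encodes the Braak-by-CERAD dichotomy", {
  expect_equal(niaaa_likelihood("0", "none"), "low")
  expect_equal(niaaa_likelihood("VI", "frequent"), "high")
  expect_equal(niaaa_likelihood("II", "moderate"), "low")
  expect_equal(niaaa_likelihood("III", "moderate"), "intermediate")
  expect_equal(niaaa_likelihood("V", "sparse"), "intermediate")
  expect_equal(niaaa_likelihood("VI", "none"), "low")
  expect_equal(niaaa_likelihood(6, "frequent"), "high")  # integer stages accepted
  expect_error(niaaa_likelihood("VII", "none"), "Braak")
  expect_error(niaaa_likelihood("I", "lots"), "CERAD")
  # full default matrix, frozen
  m <- default_niaaa_matrix()
  expect_equal(unname(m["V-VI", ]), c("low", "intermediate", "high", "high"))
  expect_equal(unname(m["III-IV", ]), c("low", "low", "intermediate", "intermediate"))
  expect_equal(unname(m["0-II", ]), rep("low", 4))
  # a custom mapping is honoured
  m2 <- m
  m2["0-II", "none"] <- "high"
  expect_equal(niaaa_likelihood("0", "none", mapping = m2), "high")
})

test_that("outcome derivation applies strict >0 rules and missing propagation", {
  panel <- data.frame(
    amyloid_load = c(0, 0.4, NA),
    tangle_count = c(3, 0, 1),
    caa_percent = c(12, 0, 0),
    macroinfarct_count = c(2, 0, 0),
    cortical_macroinfarct_count = c(1, 0, 0),
    wm_macroinfarct_count = c(0, 0, 0),
    microinfarct_count = c(0, 1, 0),
    alpha_synuclein = c("limbic", "absent", "diffuse_neocortical"),
    hs_severity = c("no_minor", "severe_marked_total", NA),
    tdp43_positive = c(TRUE, FALSE, NA),
    braak_stage = c("VI", "I", "III"),
    cerad_score = c("frequent", "none", "moderate")
  )
  d <- derive_outcomes(panel)
  expect_equal(d$outcome_amyloid, c(0, 1, NA))
  expect_equal(d$outcome_tangles, c(1, 0, 1))
  expect_equal(d$outcome_caa, c(1, 0, 0))
  expect_equal(d$outcome_macroinfarcts, c(1, 0, 0))
  expect_equal(d$outcome_cortical_macroinfarcts, c(1, 0, 0))
  expect_equal(d$outcome_wm_macroinfarcts, c(0, 0, 0))
  expect_equal(d$outcome_microinfarcts, c(0, 1, 0))
  expect_equal(d$outcome_alpha_synuclein, c(1, 0, 1))
  expect_equal(d$outcome_hs, c(0, 1, NA))
  expect_equal(d$outcome_tdp43, c(1, 0, NA))
  expect_equal(d$outcome_neuropath_ad, c(1, 0, 1))
  # deterministic and idempotent
  expect_identical(derive_outcomes(d[names(panel)]), d)
  expect_error(derive_outcomes(data.frame(macroinfarct_count = -1)),
               "non-negative")
  expect_error(derive_outcomes(data.frame(microinfarct_count = 1.5)),
               "integral")
})

test_that("centered PCA matches an independent eigendecomposition", {
  x <- matrix(c(2, 4, 6, 8, 10,
                1, 3, 2, 5, 4,
                9, 7, 8, 6, 5), ncol = 3)
  p <- run_pca(x)
  o <- oracle_pca(x)
  expect_equal(p$variance_explained, o$values / sum(o$values))
  for (j in 1:3) {
    expect_equal(abs(p$scores[, j]), abs(o$scores[, j]), tolerance = 1e-8)
  }
  # reconstruction: centered matrix = scores %*% t(loadings)
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), unclass(xc),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-8)
  expect_equal(unname(colMeans(p$scores)), rep(0, 3), tolerance = 1e-10)
  # sign convention: dominant loading of each component is positive
  for (j in 1:3) expect_gt(max(p$loadings[, j]), 0)
  expect_equal(unname(p$loadings[which.max(abs(p$loadings[, 1])), 1]),
               max(abs(p$loadings[, 1])))
})

test_that("PCA handles dominant variables, constant columns and missing rows", {
  set.seed(41)
  big <- rnorm(30, sd = 10)
  x <- cbind(a = big, b = rnorm(30, sd = 0.01), c = rnorm(30, sd = 0.01))
  p <- run_pca(x)
  expect_equal(which.max(abs(p$loadings[, 1])), c(a = 1))
  expect_gt(p$variance_explained[1], 0.99)

  x2 <- cbind(x, const = 5)
  p2 <- run_pca(x2)
  expect_equal(unname(p2$scores[, 1]), unname(p$scores[, 1]))
  expect_equal(p2$variance_explained[1:3], p$variance_explained[1:3])

  x3 <- x
  x3[c(2, 7), 1] <- NA
  p3 <- run_pca(x3)
  expect_equal(p3$n_dropped, 2)
  expect_equal(nrow(p3$scores), 28)
  expect_error(run_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("PC scores are assessed as dementia predictors with orientation flag", {
  set.seed(43)
  x <- matrix(rnorm(200), ncol = 4)
  x[, 1] <- x[, 1] * 5
  p <- run_pca(x)
  y <- as.numeric(p$scores[, 1] > median(p$scores[, 1]))
  res <- pc_dementia_auc(p, y)
  expect_equal(res$auc[1], 1)
  y_perm <- sample(y)
  res2 <- pc_dementia_auc(p, y_perm)
  expect_true(all(abs(res2$auc - 0.5) < 0.35))
  expect_equal(res2$inverted, res2$auc < 0.5)
  expect_error(pc_dementia_auc(p, rep(1, nrow(p$scores))), "single class")
  expect_error(pc_dementia_auc(p, y[-1]), "align")
})
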