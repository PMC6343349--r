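specs2 <- list(
  variable_spec("mmse", "ordinal", "cognition"),
  variable_spec("age", "continuous", "sociodemographics")
)

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("read_cohort parses valid files and applies the missing-token rule", {
  f <- write_csv_fixture(c(
    "subject_id,outcome,mmse,age",
    "s1,1,25,88",
    "s2,0,28,87",
    "s3,0,22,90"
  ))
  co <- read_cohort(f, specs2)
  expect_s3_class(co, "dsi_cohort")
  expect_equal(nrow(co), 3)
  expect_equal(attr(co, "n_warnings"), 0L)
  expect_equal(co$mmse, c(25, 28, 22))

  f2 <- write_csv_fixture(c(
    "subject_id,outcome,mmse,age",
    "s1,1,,88",
    "s2,0,28,87"
  ))
  co2 <- read_cohort(f2, specs2)
  expect_true(is.na(co2$mmse[1]))
  expect_equal(attr(co2, "n_warnings"), 0L)  # empty token is clean missing

  f3 <- write_csv_fixture(c(
    "subject_id,outcome,mmse,age",
    "s1,1,notanumber,88"
  ))
  expect_warning(co3 <- read_cohort(f3, specs2), "1 cell")
  expect_true(is.na(co3$mmse[1]))
  expect_equal(attr(co3, "n_warnings"), 1L)
})

test_that("read_cohort rejects unknown columns and duplicate ids", {
  f <- write_csv_fixture(c(
    "subject_id,outcome,mmse,age,shoe_size",
    "s1,1,25,88,43"
  ))
  expect_error(read_cohort(f, specs2), "shoe_size")
  f2 <- write_csv_fixture(c(
    "subject_id,outcome,mmse,age",
    "s1,1,25,88",
    "s1,0,28,87"
  ))
  expect_error(read_cohort(f2, specs2), "duplicate subject_id")
})

test_that("inclusion filters reproduce the study accounting and are idempotent", {
  n <- 339
  co <- data.frame(
    subject_id = paste0("s", 1:n),
    outcome = c(rep(1, 97), rep(0, 148), rep(NA, 94)),
    baseline_dementia = FALSE,
    died_within_2y = c(rep(FALSE, 245), rep(TRUE, 94)),
    autopsy_available = TRUE
  )
  co <- structure(co, class = c("dsi_cohort", "data.frame"))
  f <- apply_inclusion_filters(co, "dementia")
  expect_equal(nrow(f), 245)
  expect_equal(unname(attr(f, "exclusions")), c(0, 94))
  f2 <- apply_inclusion_filters(f, "dementia")
  expect_equal(nrow(f2), 245)
  expect_equal(f2$subject_id, f$subject_id)

  co$baseline_dementia[1] <- TRUE
  expect_equal(nrow(apply_inclusion_filters(co, "dementia")), 244)
  expect_equal(nrow(apply_inclusion_filters(co, "pathology")), 338)

  co$autopsy_available <- NULL
  expect_error(apply_inclusion_filters(co, "pathology"), "autopsy_available")

  no_flags <- data.frame(subject_id = "a", outcome = 1,
                         baseline_dementia = FALSE, died_within_2y = FALSE)
  expect_equal(nrow(apply_inclusion_filters(no_flags, "dementia")), 1)
})

test_that("APOE factors are derived per carrier definitions", {
  d <- derive_apoe_factors(c("e2e4", "e3e3", NA, "e2e3"))
  expect_equal(d$apoe_e2_carrier, c(1, 0, NA, 1))
  expect_equal(d$apoe_e4_carrier, c(1, 0, NA, 0))
  expect_equal(d$apoe_e3e3, c(0, 1, NA, 0))
  expect_error(derive_apoe_factors("e5e5"), "unknown APOE genotype")
  # epsilon glyphs are accepted
  expect_equal(derive_apoe_factors("ε2ε4")$apoe_e4_carrier, 1)
  # carrier status excludes the e3e3 homozygote by construction
  for (g in c("e2e2", "e2e3", "e2e4", "e3e4", "e4e4")) {
    dd <- derive_apoe_factors(g)
    expect_true(dd$apoe_e2_carrier + dd$apoe_e4_carrier >= 1)
    expect_equal(dd$apoe_e3e3, 0)
  }
})

test_that("a generated cohort round-trips through CSV", {
  co <- generate_cohort(default_params("dementia"), seed = 13)
  f <- tempfile(fileext = ".csv")
  write.csv(co, f, row.names = FALSE, na = "")
  co2 <- read_cohort(f, attr(co, "specs"))
  expect_equal(attr(co2, "n_warnings"), 0L)
  expect_identical(co2$died_within_2y, co$died_within_2y)
  expect_identical(co2$baseline_dementia, co$baseline_dementia)
  expect_equal(co2$outcome, co$outcome)
  expect_equal(co2$mmse_total, co$mmse_total)
  expect_equal(co2$apoe_genotype, co$apoe_genotype)
  expect_equal(nrow(apply_inclusion_filters(co2, "dementia")), 245)
})

test_that("hierarchy round-trips through YAML config", {
  h <- dsi_hierarchy(list(
    variable_spec("mmse", "ordinal", "cognition"),
    variable_spec("apoe_e4_carrier", "binary", "apoe",
                  screen_with = "apoe_genotype"),
    variable_spec("apoe_genotype", "categorical", "apoe")
  ))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(groups = lapply(h, function(g) list(
    name = g$name,
    variables = lapply(g$variables, function(v) {
      out <- list(name = v$name, kind = v$kind)
      if (!is.null(v$screen_with)) out$screen_with <- v$screen_with
      out
    })
  ))), f)
  h2 <- read_hierarchy(f)
  expect_equal(names(h2), names(h))
  expect_equal(
    vapply(hierarchy_specs(h2), `[[`, character(1), "name"),
    vapply(hierarchy_specs(h), `[[`, character(1), "name")
  )
  expect_equal(hierarchy_specs(h2)[[2]]$screen_with, "apoe_genotype")
})
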