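csp <- variable_spec("x", "continuous", "g")

test_that("relevance hits the overlap endpoints and the brute-force value", {
  expect_identical(fit_factor(c(1, 2, 3, 4), c(1, 2, 3, 4), csp)$relevance, 0)
  expect_identical(fit_factor(c(5, 6, 7, 8), c(1, 2, 3, 4), csp)$relevance, 1)
  # partial overlap, frozen against the explicit confusion-matrix scan
  expect_equal(fit_factor(c(3, 4, 5), c(1, 2, 3), csp)$relevance, 2 / 3)
  expect_equal(oracle_relevance(c(3, 4, 5), c(1, 2, 3)), 2 / 3)
})

test_that("fitness is 0/1 at class-unique tails and interpolates between", {
  m <- fit_factor(c(5, 6, 7), c(1, 2, 3), csp)
  expect_identical(fitness_value(m, 1), 0)
  expect_identical(fitness_value(m, 7), 1)
  expect_identical(fitness_value(m, 0), 0)   # clamped below support
  expect_identical(fitness_value(m, 9), 1)   # clamped above support
  # midway between support points: linear interpolation
  f2 <- fitness_value(m, 2)
  f3 <- fitness_value(m, 3)
  expect_equal(fitness_value(m, 2.5), (f2 + f3) / 2)
  expect_true(is.na(fitness_value(m, NA)))
})

test_that("fit_factor relevance equals the brute-force scan on small samples", {
  grid <- 1:5
  sets <- unlist(lapply(1:3, multisets, grid = grid), recursive = FALSE)
  for (cs in sets) for (ct in sets) {
    expect_equal(fit_factor(cs, ct, csp)$relevance, oracle_relevance(cs, ct),
                 info = paste("cases", paste(cs, collapse = ","),
                              "controls", paste(ct, collapse = ",")))
  }
})

test_that("relevance and fitness are invariant under monotone transforms", {
  set.seed(11)
  for (i in 1:20) {
    cs <- round(rnorm(8, 1), 2)
    ct <- round(rnorm(8), 2)
    tr <- function(x) exp(x) + x^3  # strictly increasing
    m1 <- fit_factor(cs, ct, csp)
    m2 <- fit_factor(tr(cs), tr(ct), csp)
    expect_equal(m1$relevance, m2$relevance)
    expect_equal(m1$orientation, m2$orientation)
    expect_equal(fitness_value(m2, tr(m1$support)), m1$fitness)
  }
})

test_that("categorical factors get frequency-ratio fitness and Youden relevance", {
  sp <- variable_spec("cat", "categorical", "g")
  m <- fit_factor(c("a", "a", "b"), c("b", "b", "c"), sp)
  expect_equal(m$categories, c("a", "b", "c"))
  expect_equal(m$fitness, c(1, (1 / 3) / (1 / 3 + 2 / 3), 0))
  # rule "case iff fitness > 0.5": sens 2/3, spec 1 -> J = 2/3
  expect_equal(m$relevance, 2 / 3)
  expect_identical(fit_factor(c("a", "b"), c("a", "b"), sp)$relevance, 0)
  expect_identical(fit_factor(c("a", "a"), c("b", "b"), sp)$relevance, 1)
  expect_warning(v <- fitness_value(m, "zz"), "unseen")
  expect_true(is.na(v))
  expect_error(fitness_value(m, "zz", unseen = "error"), "unseen")
})

test_that("degenerate factors: empty class errors, zero variance gives relevance 0", {
  expect_error(fit_factor(numeric(0), 1:3, csp), "per class")
  expect_error(fit_factor(c(NA, NA), 1:3, csp), "per class")
  expect_identical(fit_factor(c(2, 2), c(2, 2), csp)$relevance, 0)
})

test_that("aggregate_group follows the relevance-weighted missing-data contract", {
  expect_equal(aggregate_group(0.8, 0.4), 0.8)
  expect_equal(aggregate_group(c(0.2, 0.6), c(0.7, 0.7)), 0.4)
  expect_equal(aggregate_group(c(0.2, NA, 0.6), c(0.5, 0.9, 0.5)), 0.4)
  expect_true(is.na(aggregate_group(c(NA_real_, NA_real_), c(1, 1))))
  expect_equal(aggregate_group(c(0.2, 0.8), c(0, 0)), 0.5)  # all-zero weights
  expect_equal(aggregate_group(c(0.1, 0.9), c(1, 3)), 0.7)
  expect_error(aggregate_group(c(0.1, 0.9), c(1, -1)), "non-negative")
  expect_error(aggregate_group(c(0.1), c(1, 2)), "equal length")
})

test_that("a perfectly separating factor yields perfect training separation", {
  h <- dsi_hierarchy(list(variable_spec("x", "continuous", "g")))
  co <- data.frame(outcome = rep(c(1, 0), each = 5),
                   x = c(6:10, 1:5))
  m <- fit_model(co, h)
  s <- score(m, co)
  expect_true(min(s[co$outcome == 1]) > max(s[co$outcome == 0]))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("duplicating a factor within its group leaves group values unchanged", {
  co <- tiny_cohort()
  h1 <- dsi_hierarchy(list(variable_spec("a1", "continuous", "ga"),
                           variable_spec("b1", "continuous", "gb")))
  co2 <- co
  co2$a1_copy <- co2$a1
  h2 <- dsi_hierarchy(list(variable_spec("a1", "continuous", "ga"),
                           variable_spec("a1_copy", "continuous", "ga"),
                           variable_spec("b1", "continuous", "gb")))
  s1 <- score(fit_model(co, h1), co, nodes = TRUE)
  s2 <- score(fit_model(co2, h2), co2, nodes = TRUE)
  expect_equal(s2$groups[, "ga"], s1$groups[, "ga"])
  expect_equal(s2$total, s1$total)
})

test_that("deleting a leaf value changes the score exactly as dropping it from the mean", {
  co <- tiny_cohort()
  h <- tiny_hierarchy()
  m <- fit_model(co, h)
  rec <- co[3, , drop = FALSE]
  full <- score(m, rec, nodes = TRUE)
  rec_na <- rec
  rec_na$a2 <- NA
  red <- score(m, rec_na, nodes = TRUE)
  rel <- vapply(m$groups$ga$leaves, `[[`, numeric(1), "relevance")
  manual <- aggregate_group(full$leaves[1, "a1"], rel[["a1"]])
  expect_equal(unname(red$groups[1, "ga"]), manual)
  # all leaves missing -> missing score
  rec_all_na <- rec
  rec_all_na[c("a1", "a2", "b1")] <- NA
  expect_true(is.na(score(m, rec_all_na)))
  # exactly one non-missing leaf -> score equals that leaf's fitness
  rec_one <- rec_all_na
  rec_one$b1 <- rec$b1
  expect_equal(score(m, rec_one), unname(full$leaves[1, "b1"]))
})

test_that("scores and relevances always lie in [0, 1]", {
  set.seed(21)
  for (i in 1:10) {
    co <- tiny_cohort(seed = i, sep = c(a1 = runif(1, 0, 3),
                                        a2 = runif(1, 0, 3), b1 = 0))
    m <- fit_model(co, tiny_hierarchy())
    expect_true(all(m$training_summary$relevance >= 0 &
                      m$training_summary$relevance <= 1))
    s <- score(m, co)
    expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
  }
})

test_that("model serialization round-trips scores exactly", {
  co <- generate_cohort(default_params("dementia"), seed = 3)
  co <- apply_inclusion_filters(co, "dementia")
  h <- default_hierarchy("dementia")
  m <- fit_model(co, h)
  js <- dsi_model_to_json(m)
  m2 <- dsi_model_from_json(js)
  expect_equal(score(m2, co), score(m, co))
  f <- tempfile(fileext = ".json")
  dsi_model_to_json(m, f)
  m3 <- dsi_model_from_json(f)
  expect_equal(score(m3, co), score(m, co))
})
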