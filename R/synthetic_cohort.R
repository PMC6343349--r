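# Synthetic cohort generation emulating the baseline structure of an
# 85+ population study: per-outcome-group variable distributions, APOE
# genotype frequencies, pathology prevalences and missing-data counts, so
# that every pipeline stage can be exercised without subject-level data.

#' Declare a truncated-normal synthetic variable
#'
#' At generation time the underlying normal location is calibrated (per
#' group) so that the truncated distribution's mean matches the requested
#' target mean; the nominal sd is used as the underlying scale.
#'
#' @param name,group Variable and concept-group name.
#' @param mean,sd Target mean and sd; length 2 `(control, case)` or length 1
#'   recycled.
#' @param lower,upper Truncation bounds.
#' @param kind `"continuous"` or `"ordinal"` (ordinal values are rounded to
#'   integers on the truncated support).
#' @return A synthetic-variable description (list).
#' @export
synth_normal <- function(name, group, mean, sd, lower = -Inf, upper = Inf,
                         kind = c("continuous", "ordinal")) {
  kind <- match.arg(kind)
  list(name = name, group = group, dist = "normal", kind = kind,
       mean = rep_len(mean, 2L), sd = rep_len(sd, 2L),
       lower = lower, upper = upper)
}

#' Declare a Bernoulli synthetic variable
#' @param name,group Variable and concept-group name.
#' @param p Success probability; length 2 `(control, case)` or length 1.
#' @return A synthetic-variable description (list).
#' @export
synth_bernoulli <- function(name, group, p) {
  p <- rep_len(p, 2L)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  list(name = name, group = group, dist = "bernoulli", kind = "binary", p = p)
}

#' Declare a categorical synthetic variable
#' @param name,group Variable and concept-group name.
#' @param levels Category labels.
#' @param p_control,p_case Per-group probability vectors (normalized).
#' @return A synthetic-variable description (list).
#' @export
synth_categorical <- function(name, group, levels, p_control, p_case = p_control) {
  if (length(p_control) != length(levels) || length(p_case) != length(levels)) {
    stop("probability vectors must match levels", call. = FALSE)
  }
  if (any(p_control < 0) || any(p_case < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  list(name = name, group = group, dist = "categorical", kind = "categorical",
       levels = levels,
       prob = rbind(control = p_control / sum(p_control),
                    case = p_case / sum(p_case)))
}

#' Assemble synthetic-cohort parameters
#'
#' @param model_kind `"dementia"` or `"pathology"`.
#' @param n_cases,n_controls Exact class counts for the analysis population.
#' @param variables List of [synth_normal()]/[synth_bernoulli()]/
#'   [synth_categorical()] descriptions.  A variable named `apoe_genotype`
#'   additionally yields the derived carrier binaries.
#' @param missing_counts Named integer vector: exact number of missing cells
#'   to inject per variable among analysis subjects.
#' @param n_died_within_2y Extra subjects flagged as dying within two years
#'   of follow-up (excluded by the dementia-model filter; drawn from control
#'   distributions with missing outcome).
#' @param n_baseline_dementia Extra subjects flagged with baseline dementia.
#' @param follow_up Optional [synth_normal()] description for
#'   `follow_up_years`.
#' @param copula Optional correlation matrix (named rows/cols, a subset of
#'   the normal-family variables) imposing a Gaussian copula between them;
#'   variables not listed stay independent.
#' @param pathology Optional list of pathology-generation settings (see
#'   [default_params()]).
#' @return A `dsi_synth_params` object.
#' @export
synthetic_params <- function(model_kind = c("dementia", "pathology"),
                             n_cases, n_controls, variables,
                             missing_counts = integer(),
                             n_died_within_2y = 0L, n_baseline_dementia = 0L,
                             follow_up = NULL, copula = NULL,
                             pathology = NULL) {
  model_kind <- match.arg(model_kind)
  nms <- vapply(variables, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names", call. = FALSE)
  names(variables) <- nms
  if (!is.null(copula)) {
    if (is.null(rownames(copula)) ||
        !all(rownames(copula) %in% nms)) {
      stop("copula rows/cols must name declared variables", call. = FALSE)
    }
    ev <- eigen(copula, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("copula matrix must be positive semi-definite", call. = FALSE)
    }
  }
  structure(
    list(model_kind = model_kind, n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls), variables = variables,
         missing_counts = missing_counts,
         n_died_within_2y = as.integer(n_died_within_2y),
         n_baseline_dementia = as.integer(n_baseline_dementia),
         follow_up = follow_up, copula = copula, pathology = pathology),
    class = "dsi_synth_params"
  )
}

#' Default synthetic-cohort parameters
#'
#' The dementia defaults encode the published baseline table of the modeled
#' 85+ cohort: 97 incident-dementia cases and 148 controls (245 analysis
#' subjects), 94 additional subjects dying within two years of follow-up,
#' per-group means/SDs for every baseline factor, the APOE genotype
#' frequency vectors, and the printed missing-data counts (3 education,
#' 3 APOE genotype).  The pathology defaults describe the 163-subject
#' autopsy population: marginal covariate distributions (mean age 88.7,
#' 4.3 years of education, 19% men, 21% epsilon-4 and 17% epsilon-2
#' carriers, 36% dementia at death), per-outcome pathology prevalences, and
#' the generation settings linking an AD-type latent factor to amyloid,
#' tangle and CAA pathology, APOE and dementia.
#'
#' @param model_kind `"dementia"` or `"pathology"`.
#' @return A `dsi_synth_params` object.
#' @export
default_params <- function(model_kind = c("dementia", "pathology")) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "dementia") {
    vars <- list(
      synth_normal("age", "sociodemographics", c(88.4, 88.3), 2.6, 85, 105),
      synth_bernoulli("male", "sociodemographics", c(0.22, 0.20)),
      synth_normal("education", "sociodemographics", c(4.6, 3.7), c(3.3, 2.0), 0, 20),
      synth_normal("social_class", "sociodemographics", c(6.0, 6.2), c(1.5, 1.3),
                   1, 10, kind = "ordinal"),
      synth_normal("mmse_total", "cognition", c(25.3, 22.2), c(3.3, 4.5),
                   0, 30, kind = "ordinal"),
      synth_normal("mmse_calculation", "cognition", c(3.4, 2.9), 1.6,
                   0, 5, kind = "ordinal"),
      synth_normal("mmse_orientation", "cognition", c(9.5, 8.7), c(0.8, 1.6),
                   0, 10, kind = "ordinal"),
      synth_normal("mmse_other", "cognition", c(7.4, 6.7), c(1.2, 1.4),
                   0, 9, kind = "ordinal"),
      synth_normal("mmse_wordlist", "cognition", c(5.0, 4.2), c(1.1, 1.3),
                   0, 6, kind = "ordinal"),
      synth_normal("spmsq", "cognition", c(0.8, 1.8), c(1.4, 1.9),
                   0, 10, kind = "ordinal"),
      synth_normal("adl_iadl_sum", "functioning", c(29.7, 31.6), c(10.2, 10.1),
                   0, 100),
      synth_normal("competence_daily_activities", "functioning", c(2.6, 3.2),
                   c(1.3, 1.4), 1, 6, kind = "ordinal"),
      synth_normal("subjective_memory_decline", "functioning", c(1.7, 1.9),
                   c(0.6, 0.7), 1, 3, kind = "ordinal"),
      synth_categorical("apoe_genotype", "apoe", apoe_genotypes,
                        p_control = c(0, 17, 1, 101, 27, 0) / 146,
                        p_case = c(0, 18, 5, 53, 18, 1) / 95),
      synth_bernoulli("cardiovascular", "comorbidity", c(0.77, 0.68)),
      synth_bernoulli("cerebrovascular", "comorbidity", c(0.15, 0.20)),
      synth_bernoulli("diabetes", "comorbidity", c(0.20, 0.29)),
      synth_normal("total_cholesterol", "cholesterol", c(5.9, 5.7), c(1.3, 1.1),
                   1, 15),
      synth_normal("ldl_cholesterol", "cholesterol", c(4.0, 3.8), c(1.2, 1.0),
                   0.5, 12),
      synth_normal("hdl_cholesterol", "cholesterol", c(1.0, 1.1), 0.3, 0.2, 4),
      synth_normal("systolic_bp", "blood_pressure", c(161, 157), c(25, 27),
                   70, 260),
      synth_normal("diastolic_bp", "blood_pressure", c(85, 84), c(11, 12),
                   40, 160),
      synth_normal("bmi", "lifestyle", c(25.4, 24.9), c(4.4, 3.6), 12, 60),
      synth_bernoulli("no_alcohol", "lifestyle", c(0.67, 0.69)),
      synth_bernoulli("nonsmoker", "lifestyle", c(0.97, 0.98)),
      synth_normal("zung_depression", "depressive_symptoms", c(26.8, 26.7),
                   c(5.8, 5.5), 20, 80)
    )
    synthetic_params(
      "dementia", n_cases = 97L, n_controls = 148L, variables = vars,
      missing_counts = c(education = 3L, apoe_genotype = 3L),
      n_died_within_2y = 94L,
      follow_up = synth_normal("follow_up_years", "aux", c(5.4, 5.8),
                               c(2.7, 2.6), 2, 12)
    )
  } else {
    vars <- list(
      synth_normal("age", "sociodemographics", 88.7, 2.6, 85, 105),
      synth_bernoulli("male", "sociodemographics", 0.19),
      synth_normal("education", "sociodemographics", 4.3, 3.0, 0, 20),
      synth_normal("social_class", "sociodemographics", 6.1, 1.4, 1, 10,
                   kind = "ordinal"),
      synth_normal("mmse_total", "cognition", 23.5, 4.5, 0, 30, kind = "ordinal"),
      synth_normal("mmse_wordlist", "cognition", 4.4, 1.3, 0, 6, kind = "ordinal"),
      synth_normal("mmse_other", "cognition", 6.8, 1.5, 0, 9, kind = "ordinal"),
      synth_normal("spmsq", "cognition", 1.3, 1.7, 0, 10, kind = "ordinal"),
      synth_normal("competence_daily_activities", "functioning", 3.0, 1.4,
                   1, 6, kind = "ordinal"),
      synth_normal("subjective_memory_decline", "functioning", 1.8, 0.7,
                   1, 3, kind = "ordinal"),
      synth_categorical("apoe_genotype", "apoe", apoe_genotypes,
                        p_control = c(0, 0.155, 0.015, 0.635, 0.19, 0.005)),
      synth_bernoulli("cardiovascular", "comorbidity", 0.73),
      synth_bernoulli("cerebrovascular", "comorbidity", 0.18),
      synth_normal("total_cholesterol", "cholesterol", 5.8, 1.3, 1, 15),
      synth_normal("ldl_cholesterol", "cholesterol", 3.8, 1.1, 0.5, 12),
      synth_normal("hdl_cholesterol", "cholesterol", 1.0, 0.3, 0.2, 4),
      synth_normal("bmi", "lifestyle", 25.0, 4.2, 12, 60),
      synth_bernoulli("nonsmoker", "lifestyle", 0.97),
      synth_normal("zung_depression", "depressive_symptoms", 27.0, 5.7, 20, 80)
    )
    synthetic_params(
      "pathology", n_cases = 59L, n_controls = 104L, variables = vars,
      missing_counts = c(apoe_genotype = 4L, mmse_total = 5L,
                         subjective_memory_decline = 6L, education = 3L,
                         social_class = 1L, nonsmoker = 1L,
                         zung_depression = 3L, total_cholesterol = 10L,
                         bmi = 39L),
      follow_up = synth_normal("follow_up_years", "aux", 4.1, 2.5, 0, 11),
      pathology = list(
        prevalence = c(amyloid = 126 / 163, tangles = 99 / 163,
                       neuropath_ad = 77 / 163, caa = 103 / 159,
                       macroinfarcts = 80 / 163, microinfarcts = 26 / 156,
                       alpha_synuclein = 0.30, hs = 11 / 162, tdp43 = 21 / 160),
        p_cortical_given_macro = (47 / 163) / (80 / 163),
        p_wm_given_macro = (23 / 163) / (80 / 163),
        magnitudes = list(
          amyloid_load = c(meanlog = log(12), sdlog = 0.7),
          tangle_count = c(meanlog = log(8), sdlog = 0.8),
          caa_percent = c(meanlog = log(25), sdlog = 0.7)
        ),
        ad_trio_correlation = 0.6,
        apoe_latent_cor = 0.4,
        dementia_prevalence = 59 / 163,
        dementia_latent_cor = 0.5,
        panel_missing = c(caa_percent = 4L, microinfarct_count = 4L,
                          hs_severity = 1L, tdp43_positive = 3L)
      )
    )
  }
}

#' Null synthetic parameters (no group separation)
#'
#' Every factor is identically distributed in cases and controls; used for
#' calibration checks of the screening and cross-validation stages.
#'
#' @param n_cases,n_controls Class counts.
#' @param n_factors Number of standard-normal factors (grouped in pairs).
#' @return A `dsi_synth_params` object.
#' @export
null_params <- function(n_cases = 50L, n_controls = 50L, n_factors = 4L) {
  vars <- lapply(seq_len(n_factors), function(i) {
    synth_normal(sprintf("f%02d", i), sprintf("g%02d", (i + 1L) %/% 2L), 0, 1)
  })
  synthetic_params("dementia", n_cases, n_controls, vars,
                   n_died_within_2y = 0L)
}

#' Model hierarchy implied by synthetic parameters
#'
#' Builds the two-level hierarchy from the declared variables' concept
#' groups; an `apoe_genotype` variable expands to the genotype factor plus
#' the three derived carrier binaries, which inherit the genotype's
#' screening test.
#'
#' @param params A `dsi_synth_params`.
#' @return A `dsi_hierarchy`.
#' @export
params_hierarchy <- function(params) {
  stopifnot(inherits(params, "dsi_synth_params"))
  specs <- list()
  for (v in params$variables) {
    if (v$name == "apoe_genotype") {
      specs <- c(specs, list(
        variable_spec("apoe_e2_carrier", "binary", v$group,
                      screen_with = "apoe_genotype"),
        variable_spec("apoe_e4_carrier", "binary", v$group,
                      screen_with = "apoe_genotype"),
        variable_spec("apoe_e3e3", "binary", v$group,
                      screen_with = "apoe_genotype"),
        variable_spec("apoe_genotype", "categorical", v$group)
      ))
    } else {
      specs <- c(specs, list(variable_spec(v$name, v$kind, v$group)))
    }
  }
  dsi_hierarchy(specs)
}

#' Default model hierarchy
#' @param model_kind `"dementia"` or `"pathology"`.
#' @return The `dsi_hierarchy` implied by [default_params()].
#' @export
default_hierarchy <- function(model_kind = c("dementia", "pathology")) {
  params_hierarchy(default_params(model_kind))
}

# Calibrate the underlying normal location so the truncated mean hits target.
calibrate_trunc_mu <- function(target, sd, lower, upper) {
  if (sd == 0 || (!is.finite(lower) && !is.finite(upper))) return(target)
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    b <- (upper - mu) / sd
    den <- stats::pnorm(b) - stats::pnorm(a)
    if (den <= 0) return(if (a > 0) lower else upper)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / den
  }
  if (target <= lower || target >= upper) {
    stop(sprintf("target mean %g outside truncation bounds [%g, %g]",
                 target, lower, upper), call. = FALSE)
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 lower = target - 8 * sd, upper = target + 8 * sd,
                 tol = 1e-8)$root
}

draw_normal_from_u <- function(u, v, grp) {
  mu <- calibrate_trunc_mu(v$mean[grp], v$sd[grp], v$lower, v$upper)
  if (v$sd[grp] == 0) return(rep(v$mean[grp], length(u)))
  plo <- stats::pnorm(v$lower, mu, v$sd[grp])
  phi <- stats::pnorm(v$upper, mu, v$sd[grp])
  if (phi - plo <= 0) stop("infeasible truncation for ", v$name, call. = FALSE)
  x <- stats::qnorm(plo + u * (phi - plo), mu, v$sd[grp])
  if (v$kind == "ordinal") x <- pmin(pmax(round(x), v$lower), v$upper)
  x
}

draw_variable <- function(v, n, grp, u = NULL) {
  # grp: 1 = control, 2 = case
  switch(v$dist,
    normal = draw_normal_from_u(u %||% stats::runif(n), v, grp),
    bernoulli = as.numeric(stats::runif(n) < v$p[grp]),
    categorical = sample(v$levels, n, replace = TRUE, prob = v$prob[grp, ]),
    stop("unknown distribution ", v$dist, call. = FALSE)
  )
}

draw_group_block <- function(params, n, grp) {
  # Correlated uniforms for copula members, independent otherwise.
  out <- list()
  cop_vars <- if (!is.null(params$copula)) rownames(params$copula) else character()
  u_mat <- NULL
  if (length(cop_vars) && n > 0L) {
    L <- chol(params$copula + diag(1e-10, nrow(params$copula)))
    z <- matrix(stats::rnorm(n * length(cop_vars)), n) %*% L
    u_mat <- stats::pnorm(z)
    colnames(u_mat) <- cop_vars
  }
  for (v in params$variables) {
    if (v$dist == "normal" && v$name %in% cop_vars) {
      out[[v$name]] <- draw_normal_from_u(u_mat[, v$name], v, grp)
    } else {
      out[[v$name]] <- draw_variable(v, n, grp)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort table
#'
#' Draws exact class counts from the per-group variable distributions,
#' derives the APOE carrier binaries from the drawn genotypes, attaches the
#' auxiliary flags (early-death subjects carry a missing outcome and control
#' covariates; baseline-dementia subjects are flagged for exclusion), and
#' optionally injects the configured missing-data counts among analysis
#' subjects.  Deterministic given the seed.
#'
#' @param params A `dsi_synth_params`.
#' @param seed RNG seed.
#' @param inject Inject `params$missing_counts` (default `TRUE`).
#' @return A `dsi_cohort` data frame.
#' @export
generate_cohort <- function(params, seed, inject = TRUE) {
  stopifnot(inherits(params, "dsi_synth_params"))
  with_seed(seed, {
    blocks <- list(
      case = cbind(outcome = 1, died_within_2y = FALSE,
                   baseline_dementia = FALSE,
                   draw_group_block(params, params$n_cases, 2L)),
      control = cbind(outcome = 0, died_within_2y = FALSE,
                      baseline_dementia = FALSE,
                      draw_group_block(params, params$n_controls, 1L))
    )
    if (params$n_died_within_2y > 0L) {
      blocks$early <- cbind(outcome = NA_real_, died_within_2y = TRUE,
                            baseline_dementia = FALSE,
                            draw_group_block(params, params$n_died_within_2y, 1L))
    }
    if (params$n_baseline_dementia > 0L) {
      blocks$bdem <- cbind(outcome = NA_real_, died_within_2y = FALSE,
                           baseline_dementia = TRUE,
                           draw_group_block(params, params$n_baseline_dementia, 2L))
    }
    df <- do.call(rbind, blocks)
    rownames(df) <- NULL
    n <- nrow(df)
    df <- cbind(subject_id = sprintf("S%04d", seq_len(n)), df,
                stringsAsFactors = FALSE)
    df$autopsy_available <- TRUE
    if (!is.null(params$follow_up)) {
      fu <- rep(NA_real_, n)
      fu[which(df$outcome %in% 1)] <- draw_variable(params$follow_up,
                                                    sum(df$outcome %in% 1), 2L)
      fu[which(df$outcome %in% 0)] <- draw_variable(params$follow_up,
                                                    sum(df$outcome %in% 0), 1L)
      fu[is.na(df$outcome) & df$died_within_2y] <-
        stats::runif(sum(is.na(df$outcome) & df$died_within_2y), 0, 2)
      df$follow_up_years <- fu
    }
    cohort <- as_dsi_cohort(df, specs_for_params(params))
    if (inject && length(params$missing_counts)) {
      cohort <- inject_missing(cohort, params$missing_counts,
                               seed = seed + 1L,
                               rows = which(!is.na(df$outcome)))
    }
    if ("apoe_genotype" %in% names(cohort)) {
      der <- derive_apoe_factors(cohort$apoe_genotype)
      cohort$apoe_e2_carrier <- der$apoe_e2_carrier
      cohort$apoe_e4_carrier <- der$apoe_e4_carrier
      cohort$apoe_e3e3 <- der$apoe_e3e3
      cohort$apoe_genotype <- der$apoe_genotype
    }
    cohort
  })
}

specs_for_params <- function(params) {
  hierarchy_specs(params_hierarchy(params))
}

#' Inject exact per-variable missing-data counts
#'
#' Sets exactly the requested number of cells per variable to missing,
#' choosing subjects uniformly without replacement.  The outcome column is
#' never masked.
#'
#' @param cohort A cohort data frame.
#' @param missing_counts Named integer vector, variable -> count.
#' @param seed RNG seed (same seed, same mask).
#' @param rows Optional row indices eligible for masking (default all).
#' @return The cohort with masked cells.
#' @export
inject_missing <- function(cohort, missing_counts, seed, rows = NULL) {
  rows <- rows %||% seq_len(nrow(cohort))
  bad <- setdiff(names(missing_counts), names(cohort))
  if (length(bad)) {
    stop("missing_counts names not in cohort: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if ("outcome" %in% names(missing_counts)) {
    stop("the outcome column is never masked", call. = FALSE)
  }
  with_seed(seed, {
    for (v in names(missing_counts)) {
      k <- missing_counts[[v]]
      if (k > length(rows)) {
        stop(sprintf("missing count for %s (%d) exceeds eligible subjects (%d)",
                     v, k, length(rows)), call. = FALSE)
      }
      if (k > 0L) cohort[[v]][sample(rows, k)] <- NA
    }
  })
  cohort
}

#' Generate a synthetic neuropathology panel with linked baseline cohort
#'
#' Subjects share a latent AD-type severity factor: amyloid load, tangle
#' count and CAA presence/magnitude are drawn from latents correlated with
#' it at `ad_trio_correlation`; Braak stage and CERAD score are drawn
#' jointly so the derived NIA-AA likelihood dichotomy matches its configured
#' prevalence; APOE epsilon-4 carriage and dementia at death are drawn from
#' latents correlated with the same factor.  Vascular outcomes
#' (macro-/cortical/white-matter/microinfarcts) and the remaining
#' pathologies are independent with their configured prevalences, and
#' quantitative magnitudes are zero when a pathology is absent and
#' lognormal when present.
#'
#' @param params A `dsi_synth_params` with a `pathology` block (see
#'   [default_params()]).
#' @param seed RNG seed.
#' @return A list with `panel` (raw pathology measures incl. Braak/CERAD),
#'   `cohort` (baseline covariates, `outcome` = dementia at death, aux
#'   flags), and `latent` (the shared severity factor, for diagnostics).
#' @export
generate_pathology_panel <- function(params, seed) {
  stopifnot(inherits(params, "dsi_synth_params"))
  pat <- params$pathology
  if (is.null(pat)) stop("params carry no pathology block", call. = FALSE)
  prev <- pat$prevalence
  if (any(prev < 0 | prev > 1)) {
    stop("pathology prevalences must lie in [0, 1]", call. = FALSE)
  }
  n <- params$n_cases + params$n_controls
  rho <- pat$ad_trio_correlation
  with_seed(seed, {
    z <- stats::rnorm(n)  # shared AD-type severity latent
    lat <- function(r) sqrt(r) * z + sqrt(1 - r) * stats::rnorm(n)
    present_from <- function(zl, p) zl > stats::qnorm(1 - p)

    panel <- data.frame(subject_id = sprintf("P%04d", seq_len(n)),
                        stringsAsFactors = FALSE)
    mag <- function(zl, pres, par) {
      ifelse(pres, exp(par[["meanlog"]] + par[["sdlog"]] * zl), 0)
    }
    z_am <- lat(rho); am <- present_from(z_am, prev[["amyloid"]])
    panel$amyloid_load <- mag(z_am, am, pat$magnitudes$amyloid_load)
    z_tg <- lat(rho); tg <- present_from(z_tg, prev[["tangles"]])
    panel$tangle_count <- round(mag(z_tg, tg, pat$magnitudes$tangle_count))
    panel$tangle_count[tg & panel$tangle_count == 0] <- 1
    z_ca <- lat(rho); ca <- present_from(z_ca, prev[["caa"]])
    panel$caa_percent <- mag(z_ca, ca, pat$magnitudes$caa_percent)

    # Braak x CERAD drawn jointly so the derived NIA-AA dichotomy matches
    # its prevalence: sample a cell from the present/absent side of the map.
    ad <- present_from(lat(rho), prev[["neuropath_ad"]])
    map <- default_niaaa_matrix()
    cells <- expand.grid(bg = rownames(map), cerad = colnames(map),
                         stringsAsFactors = FALSE)
    cells$lik <- map[cbind(cells$bg, cells$cerad)]
    cells$w <- ifelse(cells$bg == "0-II", 3, ifelse(cells$bg == "III-IV", 2, 1))
    draw_cell <- function(present) {
      pool <- cells[(cells$lik != "low") == present, ]
      pool[sample(nrow(pool), 1L, prob = pool$w), ]
    }
    bg2stage <- list(`0-II` = c("0", "I", "II"), `III-IV` = c("III", "IV"),
                     `V-VI` = c("V", "VI"))
    braak <- character(n); cerad <- character(n)
    for (i in seq_len(n)) {
      cell <- draw_cell(ad[i])
      braak[i] <- sample(bg2stage[[cell$bg]], 1L)
      cerad[i] <- cell$cerad
    }
    panel$braak_stage <- braak
    panel$cerad_score <- cerad

    macro <- stats::runif(n) < prev[["macroinfarcts"]]
    cort <- macro & stats::runif(n) < pat$p_cortical_given_macro
    wm <- macro & stats::runif(n) < pat$p_wm_given_macro
    cort_n <- ifelse(cort, 1 + stats::rpois(n, 0.5), 0)
    wm_n <- ifelse(wm, 1 + stats::rpois(n, 0.4), 0)
    other_n <- ifelse(macro, stats::rpois(n, 0.4), 0)
    total_n <- cort_n + wm_n + other_n
    total_n[macro & total_n == 0] <- 1
    panel$macroinfarct_count <- total_n
    panel$cortical_macroinfarct_count <- cort_n
    panel$wm_macroinfarct_count <- wm_n
    micro <- stats::runif(n) < prev[["microinfarcts"]]
    panel$microinfarct_count <- ifelse(micro, 1 + stats::rpois(n, 0.8), 0)

    asyn <- stats::runif(n) < prev[["alpha_synuclein"]]
    panel$alpha_synuclein <- ifelse(
      asyn,
      sample(c("brainstem", "limbic", "diffuse_neocortical"), n, TRUE,
             prob = c(0.40, 0.35, 0.25)),
      "absent")
    panel$hs_severity <- ifelse(stats::runif(n) < prev[["hs"]],
                                "severe_marked_total", "no_minor")
    panel$tdp43_positive <- stats::runif(n) < prev[["tdp43"]]

    dementia <- as.numeric(present_from(lat(pat$dementia_latent_cor^2),
                                        pat$dementia_prevalence))

    covars <- draw_group_block(params, n, 1L)
    if ("apoe_genotype" %in% names(covars)) {
      # epsilon-4 carriage rides the AD latent; genotype within carrier
      # status follows the marginal frequencies.
      gv <- params$variables$apoe_genotype
      p <- gv$prob[1L, ]
      names(p) <- gv$levels
      p_e4 <- sum(p[c("e2e4", "e3e4", "e4e4")])
      e4 <- present_from(lat(pat$apoe_latent_cor^2), p_e4)
      g <- character(n)
      g[e4] <- sample(c("e2e4", "e3e4", "e4e4"), sum(e4), TRUE,
                      prob = p[c("e2e4", "e3e4", "e4e4")] / p_e4)
      g[!e4] <- sample(c("e2e2", "e2e3", "e3e3"), sum(!e4), TRUE,
                       prob = p[c("e2e2", "e2e3", "e3e3")] / (1 - p_e4))
      covars$apoe_genotype <- g
    }
    df <- cbind(subject_id = panel$subject_id, outcome = dementia,
                died_within_2y = FALSE, baseline_dementia = FALSE,
                autopsy_available = TRUE, covars, stringsAsFactors = FALSE)
    if (!is.null(params$follow_up)) {
      df$follow_up_years <- draw_variable(params$follow_up, n, 1L)
    }
    cohort <- as_dsi_cohort(df, specs_for_params(params))
    if (length(params$missing_counts)) {
      cohort <- inject_missing(cohort, params$missing_counts, seed = seed + 1L)
    }
    if ("apoe_genotype" %in% names(cohort)) {
      der <- derive_apoe_factors(cohort$apoe_genotype)
      cohort$apoe_e2_carrier <- der$apoe_e2_carrier
      cohort$apoe_e4_carrier <- der$apoe_e4_carrier
      cohort$apoe_e3e3 <- der$apoe_e3e3
    }
    pm <- pat$panel_missing
    if (length(pm)) {
      panel <- inject_missing(panel, pm, seed = seed + 2L)
    }
    list(panel = panel, cohort = cohort, latent = z)
  })
}
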