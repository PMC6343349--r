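# End-to-end orchestration: simulate or load a cohort, apply inclusion
# filters, screen factors, fit and cross-validate DSI models, and render
# the three-level report; pathology branch adds outcome derivation and the
# PCA stage.

#' Assemble a pipeline run configuration
#'
#' @param cohort Path to a cohort CSV, a `dsi_cohort`, or `NULL` to simulate
#'   from `params`.
#' @param panel For the pathology branch: path to a raw pathology CSV, a
#'   data frame, or `NULL` to simulate.
#' @param params Synthetic parameters used when simulating (default
#'   [default_params()] of the matching kind).
#' @param hierarchy A `dsi_hierarchy`, a config file path, or `NULL` for the
#'   default hierarchy.
#' @param cv A [cv_config()]; its seed governs fold assignment.
#' @param alpha Screening significance threshold.
#' @param seed Seed for cohort simulation.
#' @param out_dir Output directory for the report bundle (`NULL`: nothing
#'   written).
#' @param nested_screening Repeat screening inside each training fold.
#' @param verbose Log stage-boundary subject/factor accounting.
#' @return A `dsi_run_config` list.
#' @export
run_config <- function(cohort = NULL, panel = NULL, params = NULL,
                       hierarchy = NULL, cv = cv_config(), alpha = 0.05,
                       seed = 42L, out_dir = NULL, nested_screening = FALSE,
                       verbose = TRUE) {
  structure(list(cohort = cohort, panel = panel, params = params,
                 hierarchy = hierarchy, cv = cv, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 nested_screening = nested_screening, verbose = verbose),
            class = "dsi_run_config")
}

say <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

resolve_cohort <- function(config, model_kind) {
  params <- config$params %||% default_params(model_kind)
  hier <- config$hierarchy
  if (is.character(hier)) hier <- read_hierarchy(hier)
  if (is.null(hier)) hier <- params_hierarchy(params)
  if (is.null(config$cohort)) {
    cohort <- generate_cohort(params, seed = config$seed)
  } else if (is.character(config$cohort)) {
    cohort <- read_cohort(config$cohort, hierarchy_specs(hier))
  } else {
    cohort <- config$cohort
  }
  list(cohort = cohort, hierarchy = hier, params = params)
}

provenance_record <- function(config, seed_used) {
  list(seed = seed_used,
       cv = unclass(config$cv),
       alpha = config$alpha,
       nested_screening = config$nested_screening,
       package = "dsindex",
       package_version = as.character(utils::packageVersion("dsindex")),
       r_version = as.character(getRversion()),
       config_hash = json_hash(list(seed = seed_used, cv = unclass(config$cv),
                                    alpha = config$alpha)))
}

write_bundle <- function(dir, screening, report, provenance, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(screening)) {
    jsonlite::write_json(screening, file.path(dir, "screening.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
  }
  write_report(report, dir)
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(extra)) {
    jsonlite::write_json(extra[[nm]], file.path(dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
  }
  invisible(dir)
}

#' Run the dementia prediction analysis end to end
#'
#' Simulates or loads the cohort, applies the dementia-model inclusion
#' filters (no baseline dementia, survival beyond two years), screens the
#' factors at `alpha`, prunes the hierarchy, runs repeated k-fold
#' cross-validation of the DSI model and renders the three-level report.
#' When `out_dir` is set, writes `screening.json`, `results.json`,
#' `report.txt` and `provenance.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort`, `screening`, `hierarchy`
#'   (pruned), `cv` (the `dsi_cv`), `report`, `provenance`.
#' @export
run_dementia_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "dsi_run_config"))
  rc <- resolve_cohort(config, "dementia")
  cohort <- rc$cohort
  say(config$verbose, "cohort: %d subjects", nrow(cohort))
  cohort <- apply_inclusion_filters(cohort, "dementia")
  excl <- attr(cohort, "exclusions")
  say(config$verbose, "after inclusion filters: %d subjects (excluded: %s)",
      nrow(cohort), paste(names(excl), excl, sep = "=", collapse = ", "))
  analysis <- cohort[!is.na(cohort$outcome), , drop = FALSE]
  say(config$verbose, "analysis population: %d (%d cases / %d controls)",
      nrow(analysis), sum(analysis$outcome == 1), sum(analysis$outcome == 0))
  screening <- screen_factors(analysis, rc$hierarchy, alpha = config$alpha)
  hier <- prune_hierarchy(rc$hierarchy, screening)
  say(config$verbose, "screening: %d of %d factors selected (%d groups retained)",
      sum(screening$selected), nrow(screening), length(hier))
  if (length(hier) == 0L) {
    stop("no factors selected at alpha = ", config$alpha,
         "; screening table:\n",
         paste(utils::capture.output(print.data.frame(screening, digits = 3)),
               collapse = "\n"),
         call. = FALSE)
  }
  cvres <- cross_validate(analysis, hier, config$cv,
                          nested_screening = config$nested_screening,
                          alpha = config$alpha)
  report <- render_report(list(dementia = cvres))
  prov <- provenance_record(config, config$seed)
  if (!is.null(config$out_dir)) {
    write_bundle(config$out_dir, screening, report, prov)
  }
  invisible(list(cohort = cohort, screening = screening, hierarchy = hier,
                 cv = cvres, report = report, provenance = prov))
}

#' Run the neuropathology prediction analysis end to end
#'
#' Simulates or loads the autopsy cohort and raw pathology panel, derives
#' the binary pathology outcomes, and for each outcome runs the screening +
#' DSI + cross-validation loop against the baseline factors.  Outcomes with
#' no significant factors are reported as having no significant predictors;
#' outcomes with fewer than two subjects in a class are skipped with a
#' warning.  Finally runs the centered PCA of the pathology matrix and
#' assesses each component's subject scores as dementia predictors.
#'
#' @param config A [run_config()].
#' @param outcomes Outcome names to model (default: all derivable).
#' @return Invisibly, a list with `cohort`, `panel` (with derived outcome
#'   columns), per-outcome `screenings` and `results`, `pca`, `pc_auc`,
#'   `report`, `provenance`.
#' @export
run_pathology_analysis <- function(config = run_config(),
                                   outcomes = pathology_outcomes) {
  stopifnot(inherits(config, "dsi_run_config"))
  params <- config$params %||% default_params("pathology")
  hier0 <- config$hierarchy
  if (is.character(hier0)) hier0 <- read_hierarchy(hier0)
  if (is.null(hier0)) hier0 <- params_hierarchy(params)
  if (is.null(config$panel)) {
    sim <- generate_pathology_panel(params, seed = config$seed)
    panel <- sim$panel
    cohort <- sim$cohort
  } else {
    panel <- if (is.character(config$panel)) {
      utils::read.csv(config$panel, stringsAsFactors = FALSE)
    } else {
      config$panel
    }
    rc <- resolve_cohort(config, "pathology")
    cohort <- rc$cohort
    hier0 <- rc$hierarchy
  }
  cohort <- apply_inclusion_filters(cohort, "pathology")
  say(config$verbose, "autopsy population: %d subjects", nrow(cohort))
  panel <- derive_outcomes(panel)
  idx <- match(cohort$subject_id, panel$subject_id)
  results <- list()
  screenings <- list()
  for (oc in outcomes) {
    col <- paste0("outcome_", oc)
    if (!col %in% names(panel)) next
    y <- panel[[col]][idx]
    dat <- cohort
    dat$outcome <- y
    dat <- dat[!is.na(dat$outcome), , drop = FALSE]
    n1 <- sum(dat$outcome == 1)
    n0 <- sum(dat$outcome == 0)
    say(config$verbose, "outcome %s: %d present / %d absent", oc, n1, n0)
    if (n1 < 2L || n0 < 2L) {
      warning("outcome ", oc, " skipped: fewer than 2 subjects in a class",
              call. = FALSE)
      results[[oc]] <- "skipped: fewer than 2 subjects in a class"
      next
    }
    scr <- screen_factors(dat, hier0, alpha = config$alpha)
    screenings[[oc]] <- scr
    hier <- prune_hierarchy(hier0, scr)
    if (length(hier) == 0L) {
      say(config$verbose, "outcome %s: no significant predictors", oc)
      results[[oc]] <- "no significant predictors"
      next
    }
    results[[oc]] <- cross_validate(dat, hier, config$cv,
                                    nested_screening = config$nested_screening,
                                    alpha = config$alpha)
  }
  pca_vars <- c("amyloid_load", "tangle_count", "caa_percent",
                "macroinfarct_count", "microinfarct_count",
                "outcome_alpha_synuclein", "outcome_hs", "outcome_tdp43")
  pca_vars <- intersect(pca_vars, names(panel))
  pmat <- panel[idx, pca_vars, drop = FALSE]
  rownames(pmat) <- NULL
  pca <- run_pca(pmat)
  say(config$verbose, "PCA: %d complete cases (%d dropped)",
      nrow(pca$scores), pca$n_dropped)
  pc_auc <- pc_dementia_auc(pca, cohort$outcome[pca$kept_rows])
  report <- render_report(results)
  prov <- provenance_record(config, config$seed)
  if (!is.null(config$out_dir)) {
    write_bundle(config$out_dir, screenings, report, prov,
                 extra = list(pca = list(
                   variance_explained = pca$variance_explained,
                   n_complete = nrow(pca$scores),
                   pc_dementia_auc = pc_auc)))
  }
  invisible(list(cohort = cohort, panel = panel, screenings = screenings,
                 results = results, pca = pca, pc_auc = pc_auc,
                 report = report, provenance = prov))
}
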