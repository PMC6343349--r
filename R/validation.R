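# Repeated k-fold cross-validation of DSI models, rank-based AUC with 95% CI,
# and sensitivity/specificity at the fixed index cutoff.

#' Rank-based area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic divided by `n_case * n_control`;
#' ties count one half.  Equivalent to the probability that a random case
#' scores above a random control.
#'
#' @param scores Numeric scores (missing scores are dropped with their labels).
#' @param labels 0/1 outcome labels aligned with `scores`.
#' @return AUC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
#' @examples
#' auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))  # 0.75
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("one class absent; AUC is missing", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' A subject is classified case-positive when its score is greater than or
#' equal to the cutoff (ties sit on the case side, matching the index's
#' threshold convention).
#'
#' @param scores Numeric scores (missing scores are dropped).
#' @param labels 0/1 labels.
#' @param cutoff Decision threshold (default 0.5).
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec_at <- function(scores, labels, cutoff = 0.5) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!any(labels == 1) || !any(labels == 0)) {
    warning("one class absent; sensitivity/specificity missing", call. = FALSE)
    return(c(sensitivity = NA_real_, specificity = NA_real_))
  }
  pos <- scores >= cutoff
  c(sensitivity = mean(pos[labels == 1]),
    specificity = mean(!pos[labels == 0]))
}

#' Cross-validation configuration
#'
#' @param k Number of folds (>= 2; default 10).
#' @param repeats Number of independent repetitions (default 10).
#' @param seed RNG seed governing all fold assignments.
#' @param stratified Stratify fold assignment by outcome (default `FALSE`:
#'   plain random subgroups).
#' @param cutoff Index cutoff for sensitivity/specificity (default 0.5).
#' @param ci Confidence-interval method over fold-level values:
#'   `"percentile"` (2.5th-97.5th percentiles, default) or `"normal"`
#'   (mean +/- 1.96 sd, clamped to `[0, 1]`).
#' @return A `dsi_cv_config` list.
#' @export
cv_config <- function(k = 10L, repeats = 10L, seed = 42L, stratified = FALSE,
                      cutoff = 0.5, ci = c("percentile", "normal")) {
  ci <- match.arg(ci)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (repeats < 1L) stop("repeats must be at least 1", call. = FALSE)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), stratified = stratified,
                 cutoff = cutoff, ci = ci),
            class = "dsi_cv_config")
}

fold_assignment <- function(y, k, stratified) {
  n <- length(y)
  if (!stratified) {
    sample(rep_len(seq_len(k), n))
  } else {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  }
}

ci_bounds <- function(vals, method) {
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(c(NA_real_, NA_real_))
  if (method == "percentile") {
    unname(stats::quantile(vals, c(0.025, 0.975)))
  } else {
    m <- mean(vals)
    s <- stats::sd(vals)
    c(max(0, m - 1.96 * s), min(1, m + 1.96 * s))
  }
}

#' Repeated k-fold cross-validation of a Disease State Index model
#'
#' For every repetition the analysis population is split into `k` random
#' subgroups; each subgroup in turn is held out, a full DSI model (screening
#' optionally repeated on the training part) is fitted on the remaining
#' subgroups and the held-out subjects are scored.  AUC, sensitivity and
#' specificity at the fixed cutoff are computed per fold for the total index,
#' every concept group, and every individual factor, then summarized as the
#' mean with a 95% interval over the `k * repeats` fold values.
#'
#' @param cohort Cohort data frame with 0/1 `outcome`; subjects with missing
#'   outcome are dropped.
#' @param hierarchy A `dsi_hierarchy` (typically already pruned by
#'   screening).
#' @param cv A [cv_config()].
#' @param nested_screening Repeat factor screening inside every training fold
#'   (leak-free variant; default `FALSE`, matching a single pre-model
#'   screening pass).
#' @param alpha Screening threshold used when `nested_screening = TRUE`.
#' @param outcome_col Outcome column name.
#' @param .hook Optional function called per fold with a list
#'   `(repeat, fold, train_ids, test_ids)`; used for instrumentation.
#' @return A `dsi_cv` object: `summary` data frame (node, level, group, mean
#'   AUC, CI bounds, sensitivity, specificity and their CIs, n_folds), plus
#'   fold-level matrices `fold_auc`, `fold_sens`, `fold_spec`.
#' @export
cross_validate <- function(cohort, hierarchy, cv = cv_config(),
                           nested_screening = FALSE, alpha = 0.05,
                           outcome_col = "outcome", .hook = NULL) {
  stopifnot(inherits(cv, "dsi_cv_config"), inherits(hierarchy, "dsi_hierarchy"))
  if (length(hierarchy) == 0L) stop("empty hierarchy", call. = FALSE)
  y_all <- cohort[[outcome_col]]
  keep <- !is.na(y_all)
  cohort <- cohort[keep, , drop = FALSE]
  y <- y_all[keep]
  n <- nrow(cohort)
  if (sum(y == 1) < cv$k || sum(y == 0) < cv$k) {
    warning("fewer cases or controls than folds; some folds may lack a class",
            call. = FALSE)
  }
  node_names <- c("Entire model", names(hierarchy),
                  vapply(hierarchy_specs(hierarchy), `[[`, character(1), "name"))
  node_level <- c("total", rep("group", length(hierarchy)),
                  rep("factor", length(node_names) - 1 - length(hierarchy)))
  node_group <- c(NA_character_, names(hierarchy),
                  vapply(hierarchy_specs(hierarchy), `[[`, character(1), "group"))
  n_nodes <- length(node_names)
  n_folds_total <- cv$k * cv$repeats
  fold_auc <- matrix(NA_real_, n_folds_total, n_nodes,
                     dimnames = list(NULL, node_names))
  fold_sens <- fold_auc
  fold_spec <- fold_auc
  ids <- if ("subject_id" %in% names(cohort)) cohort$subject_id else seq_len(n)

  with_seed(cv$seed, {
    row <- 0L
    for (rep_i in seq_len(cv$repeats)) {
      folds <- fold_assignment(y, cv$k, cv$stratified)
      for (fold_i in seq_len(cv$k)) {
        row <- row + 1L
        test <- folds == fold_i
        if (!is.null(.hook)) {
          .hook(list(repeat_i = rep_i, fold = fold_i,
                     train_ids = ids[!test], test_ids = ids[test]))
        }
        if (length(unique(y[test])) < 2L) {
          warning(sprintf("repeat %d fold %d: single-class test fold skipped",
                          rep_i, fold_i), call. = FALSE)
          next
        }
        hier_f <- hierarchy
        if (nested_screening) {
          scr <- screen_factors(cohort[!test, , drop = FALSE], hierarchy,
                                alpha = alpha, outcome_col = outcome_col)
          hier_f <- prune_hierarchy(hierarchy, scr)
          if (length(hier_f) == 0L) {
            warning(sprintf("repeat %d fold %d: no factors selected", rep_i, fold_i),
                    call. = FALSE)
            next
          }
        }
        fit <- fit_model(cohort[!test, , drop = FALSE], hier_f,
                         outcome_col = outcome_col)
        sc <- score(fit, cohort[test, , drop = FALSE], nodes = TRUE)
        y_te <- y[test]
        node_scores <- cbind(`Entire model` = sc$total, sc$groups, sc$leaves)
        for (nd in colnames(node_scores)) {
          if (!nd %in% node_names) next
          s <- node_scores[, nd]
          fold_auc[row, nd] <- suppressWarnings(auc(s, y_te))
          ss <- suppressWarnings(sens_spec_at(s, y_te, cv$cutoff))
          fold_sens[row, nd] <- ss[["sensitivity"]]
          fold_spec[row, nd] <- ss[["specificity"]]
        }
      }
    }
  })

  summarize <- function(mat) {
    t(vapply(seq_len(n_nodes), function(j) {
      vals <- mat[, j]
      ci <- ci_bounds(vals, cv$ci)
      c(mean = mean(vals, na.rm = TRUE), lo = ci[1], hi = ci[2])
    }, numeric(3)))
  }
  sa <- summarize(fold_auc)
  ss <- summarize(fold_sens)
  sp <- summarize(fold_spec)
  summary_df <- data.frame(
    node = node_names, level = node_level, group = node_group,
    auc = sa[, "mean"], auc_ci_low = sa[, "lo"], auc_ci_high = sa[, "hi"],
    sensitivity = ss[, "mean"], sens_ci_low = ss[, "lo"], sens_ci_high = ss[, "hi"],
    specificity = sp[, "mean"], spec_ci_low = sp[, "lo"], spec_ci_high = sp[, "hi"],
    n_folds = colSums(!is.na(fold_auc)),
    stringsAsFactors = FALSE
  )
  rownames(summary_df) <- NULL
  structure(
    list(config = cv, summary = summary_df, fold_auc = fold_auc,
         fold_sens = fold_sens, fold_spec = fold_spec,
         n_subjects = n, n_cases = sum(y == 1), n_controls = sum(y == 0)),
    class = "dsi_cv"
  )
}

#' @export
print.dsi_cv <- function(x, digits = 2, ...) {
  cat(sprintf("DSI cross-validation: %d x %d-fold, %d subjects (%d cases / %d controls)\n",
              x$config$repeats, x$config$k, x$n_subjects, x$n_cases, x$n_controls))
  df <- x$summary
  fmt <- function(m, l, h) sprintf("%.*f [%.*f-%.*f]", digits, m, digits, l, digits, h)
  show <- data.frame(
    Predictor = ifelse(df$level == "factor", paste0("  ", df$node), df$node),
    `AUC [95% CI]` = fmt(df$auc, df$auc_ci_low, df$auc_ci_high),
    `Sens [95% CI]` = fmt(df$sensitivity, df$sens_ci_low, df$sens_ci_high),
    `Spec [95% CI]` = fmt(df$specificity, df$spec_ci_low, df$spec_ci_high),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(show, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Render a multi-outcome cross-validation report
#'
#' Produces the three-level table (entire model, concept groups, individual
#' factors) with AUC \[95% CI\] and sensitivity/specificity at the fixed
#' cutoff, for one or several outcomes, in both machine-readable and plain
#' text form.
#'
#' @param results A `dsi_cv` object or named list of them (one per outcome).
#' @return A `dsi_report` list with elements `text` (character lines) and
#'   `tables` (named list of summary data frames).
#' @export
render_report <- function(results) {
  if (inherits(results, "dsi_cv")) results <- list(outcome = results)
  if (length(results) == 0L) stop("no results to report", call. = FALSE)
  lines <- character()
  tables <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    if (is.character(res)) {  # e.g. "no significant predictors"
      lines <- c(lines, sprintf("== %s ==", nm), res, "")
      tables[[nm]] <- res
      next
    }
    lines <- c(lines, sprintf("== %s ==", nm),
               utils::capture.output(print(res)), "")
    tables[[nm]] <- res$summary
  }
  structure(list(text = lines, tables = tables), class = "dsi_report")
}

#' @export
print.dsi_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' @param report A `dsi_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`report.txt`, `results.json`).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dsi_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(dir, "report.txt")
  writeLines(report$text, txt)
  js <- file.path(dir, "results.json")
  jsonlite::write_json(report$tables, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(report = txt, results = js))
}
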