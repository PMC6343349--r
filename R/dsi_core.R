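# Disease State Index core: per-factor fitness curves, Youden-index
# relevance, relevance-weighted aggregation through the concept-group
# hierarchy, and the missing-data contract.

youden_sweep <- function(case_values, control_values) {
  # Max Youden index over all observed thresholds and both orientations.
  # cases_high: predict case iff value >= t (ties on the case side);
  # cases_low mirrored: predict case iff value <= t.
  thr <- sort(unique(c(case_values, control_values)))
  j_high <- vapply(thr, function(t) {
    mean(case_values >= t) + mean(control_values < t) - 1
  }, numeric(1))
  j_low <- vapply(thr, function(t) {
    mean(case_values <= t) + mean(control_values > t) - 1
  }, numeric(1))
  if (max(j_high) >= max(j_low)) {
    list(relevance = max(0, max(j_high)), orientation = "cases_high")
  } else {
    list(relevance = max(0, max(j_low)), orientation = "cases_low")
  }
}

fitness_curve <- function(case_values, control_values, support, orientation) {
  # f(x) = FNR / (FNR + FPR) at threshold x.  Both error rates count x itself
  # (a case at x contributes to FNR, a control at x to FPR), so the
  # denominator is positive at every observed support point.
  if (orientation == "cases_high") {
    fnr <- vapply(support, function(s) mean(case_values <= s), numeric(1))
    fpr <- vapply(support, function(s) mean(control_values >= s), numeric(1))
  } else {
    fnr <- vapply(support, function(s) mean(case_values >= s), numeric(1))
    fpr <- vapply(support, function(s) mean(control_values <= s), numeric(1))
  }
  fnr / (fnr + fpr)
}

#' Fit a single-factor Disease State Index model
#'
#' Learns, from the training values of cases and controls, (i) a fitness
#' curve `f(x)` giving the share of false-negative errors among all errors
#' when `x` is used as a classification threshold — so values typical of
#' controls score near 0 and values typical of cases near 1 — and (ii) the
#' factor's relevance, the maximum Youden index
#' (sensitivity + specificity − 1) over all observed thresholds and both
#' orientations.  Completely overlapping distributions get relevance 0;
#' perfectly separated ones get 1.
#'
#' Categorical (and binary) variables get a per-category fitness
#' `p_case(c) / (p_case(c) + p_control(c))` from within-class frequencies,
#' and relevance is the Youden index of the rule "predict case when
#' fitness > 1/2".
#'
#' @param case_values,control_values Training values (missing values are
#'   dropped; each class must retain at least one value).
#' @param spec The factor's [variable_spec()].
#' @return An object of class `dsi_factor` with elements `support` (or
#'   `categories`), `fitness`, `relevance`, `orientation`.
#' @export
#' @examples
#' sp <- variable_spec("x", "continuous", "g")
#' fit_factor(c(5, 6, 7), c(1, 2, 3), sp)$relevance  # disjoint -> 1
fit_factor <- function(case_values, control_values, spec) {
  stopifnot(inherits(spec, "dsi_varspec"))
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (length(case_values) == 0L || length(control_values) == 0L) {
    stop("factor '", spec$name,
         "': need at least one non-missing value per class", call. = FALSE)
  }
  if (spec$kind %in% c("continuous", "ordinal")) {
    case_values <- as.numeric(case_values)
    control_values <- as.numeric(control_values)
    sw <- youden_sweep(case_values, control_values)
    support <- sort(unique(c(case_values, control_values)))
    fit <- fitness_curve(case_values, control_values, support, sw$orientation)
    structure(
      list(variable = spec$name, kind = spec$kind, group = spec$group,
           support = support, fitness = fit,
           relevance = sw$relevance, orientation = sw$orientation),
      class = "dsi_factor"
    )
  } else {
    case_values <- as.character(case_values)
    control_values <- as.character(control_values)
    cats <- sort(unique(c(case_values, control_values)))
    p_case <- vapply(cats, function(cc) mean(case_values == cc), numeric(1))
    p_ctrl <- vapply(cats, function(cc) mean(control_values == cc), numeric(1))
    fit <- p_case / (p_case + p_ctrl)
    sens <- sum(p_case[fit > 0.5])
    spc <- sum(p_ctrl[fit <= 0.5])
    structure(
      list(variable = spec$name, kind = spec$kind, group = spec$group,
           categories = cats, fitness = unname(fit),
           relevance = max(0, sens + spc - 1), orientation = "per_category"),
      class = "dsi_factor"
    )
  }
}

#' @export
print.dsi_factor <- function(x, ...) {
  cat(sprintf("DSI factor '%s' (%s): relevance %.3f, orientation %s, %d support point(s)\n",
              x$variable, x$kind, x$relevance, x$orientation,
              length(x$support %||% x$categories)))
  invisible(x)
}

#' Evaluate a fitted fitness curve
#'
#' Continuous and ordinal factors are evaluated by piecewise-linear
#' interpolation between adjacent training support points, clamped constant
#' beyond the extremes; categorical factors by lookup.  A category never seen
#' in training is treated according to `unseen` (default: returned as missing
#' with a warning, so it simply drops out of the weighted average).
#'
#' @param model A `dsi_factor`.
#' @param x Values to evaluate (vectorized); `NA` in gives `NA` out.
#' @param unseen Policy for unseen categories: `"missing"` or `"error"`.
#' @return Numeric vector of fitness values in `[0, 1]` (or `NA`).
#' @export
fitness_value <- function(model, x, unseen = c("missing", "error")) {
  stopifnot(inherits(model, "dsi_factor"))
  unseen <- match.arg(unseen)
  if (model$kind %in% c("continuous", "ordinal")) {
    x <- as.numeric(x)
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    if (any(ok)) {
      if (length(model$support) == 1L) {
        out[ok] <- model$fitness[1L]
      } else {
        out[ok] <- stats::approx(model$support, model$fitness,
                                 xout = x[ok], rule = 2)$y
      }
    }
    out
  } else {
    x <- as.character(x)
    idx <- match(x, model$categories)
    new_cat <- !is.na(x) & is.na(idx)
    if (any(new_cat)) {
      if (unseen == "error") {
        stop("factor '", model$variable, "': unseen categor",
             if (sum(new_cat) > 1) "ies: " else "y: ",
             paste(unique(x[new_cat]), collapse = ", "), call. = FALSE)
      }
      warning("factor '", model$variable, "': ", sum(new_cat),
              " value(s) in unseen categories treated as missing", call. = FALSE)
    }
    model$fitness[idx]
  }
}

#' Relevance-weighted aggregation of child values
#'
#' Combines child fitness (or child group) values into one node value by a
#' weighted average with relevance weights.  Missing children are ignored and
#' the value is computed from the available children only; if every child is
#' missing the result is missing.  If all available children have relevance 0
#' the unweighted mean is used.
#'
#' @param values Numeric vector of child values (may contain `NA`).
#' @param relevances Non-negative weights, same length as `values`.
#' @return A single number in `[0, 1]`, or `NA` if all children are missing.
#' @export
#' @examples
#' aggregate_group(c(0.2, NA, 0.6), c(0.5, 0.9, 0.5))  # 0.4
aggregate_group <- function(values, relevances) {
  if (length(values) != length(relevances)) {
    stop("values and relevances must have equal length", call. = FALSE)
  }
  if (any(is.na(relevances)) || any(relevances < 0)) {
    stop("relevances must be non-negative and non-missing", call. = FALSE)
  }
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  v <- values[ok]
  w <- relevances[ok]
  if (sum(w) == 0) mean(v) else sum(v * w) / sum(w)
}

# Aggregate each row of a subjects x children value matrix.
aggregate_rows <- function(mat, relevances) {
  apply(mat, 1L, aggregate_group, relevances = relevances)
}

#' Fit a full Disease State Index model
#'
#' Fits a factor model for every leaf of the hierarchy, forms each concept
#' group's training value per subject by relevance-weighted averaging of its
#' member fitness values, assigns the group a relevance of its own (the
#' maximum Youden index of the group's training values against the outcome,
#' computed exactly as for an individual factor), and repeats the weighted
#' average across groups to obtain the total index.  Index values range from
#' 0 (similar to controls) to 1 (similar to cases).
#'
#' @param cohort A `dsi_cohort` (or data frame) with an `outcome` column
#'   coded 0/1 and one column per hierarchy variable.
#' @param hierarchy A `dsi_hierarchy`.
#' @param outcome_col Name of the outcome column (default `"outcome"`).
#' @return An object of class `dsi_model` with the fitted leaves, per-group
#'   relevances, and a `training_summary` data frame of per-node relevances.
#' @export
fit_model <- function(cohort, hierarchy, outcome_col = "outcome") {
  stopifnot(inherits(hierarchy, "dsi_hierarchy"))
  if (length(hierarchy) == 0L) stop("empty hierarchy", call. = FALSE)
  y <- cohort[[outcome_col]]
  if (is.null(y)) stop("cohort has no '", outcome_col, "' column", call. = FALSE)
  use <- !is.na(y)
  cohort <- cohort[use, , drop = FALSE]
  y <- y[use]
  if (sum(y == 1) < 1L || sum(y == 0) < 1L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  missing_vars <- setdiff(
    vapply(hierarchy_specs(hierarchy), `[[`, character(1), "name"),
    names(cohort)
  )
  if (length(missing_vars)) {
    stop("hierarchy variable(s) absent from cohort: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  groups <- list()
  group_scores <- matrix(NA_real_, nrow(cohort), length(hierarchy),
                         dimnames = list(NULL, names(hierarchy)))
  group_rel <- numeric(length(hierarchy))
  names(group_rel) <- names(hierarchy)
  for (g in names(hierarchy)) {
    members <- hierarchy[[g]]$variables
    leaves <- lapply(members, function(sp) {
      fit_factor(cohort[[sp$name]][y == 1], cohort[[sp$name]][y == 0], sp)
    })
    names(leaves) <- vapply(members, `[[`, character(1), "name")
    leaf_fit <- vapply(names(leaves), function(v) {
      fitness_value(leaves[[v]], cohort[[v]])
    }, numeric(nrow(cohort)))
    leaf_fit <- matrix(leaf_fit, nrow = nrow(cohort),
                       dimnames = list(NULL, names(leaves)))
    rel <- vapply(leaves, `[[`, numeric(1), "relevance")
    gs <- aggregate_rows(leaf_fit, rel)
    group_scores[, g] <- gs
    group_rel[g] <- group_relevance(gs, y, g)
    groups[[g]] <- list(name = g, leaves = leaves, relevance = group_rel[g])
  }
  total <- aggregate_rows(group_scores, group_rel)
  summary_df <- rbind(
    data.frame(node = "Entire model", level = "total", group = NA_character_,
               relevance = group_relevance(total, y, "total"),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(hierarchy), function(g) {
      rbind(
        data.frame(node = g, level = "group", group = g,
                   relevance = group_rel[[g]], stringsAsFactors = FALSE),
        data.frame(
          node = vapply(groups[[g]]$leaves, `[[`, character(1), "variable"),
          level = "factor", group = g,
          relevance = vapply(groups[[g]]$leaves, `[[`, numeric(1), "relevance"),
          stringsAsFactors = FALSE
        )
      )
    }))
  )
  rownames(summary_df) <- NULL
  structure(
    list(groups = groups, group_relevance = group_rel,
         training_summary = summary_df, outcome_col = outcome_col),
    class = "dsi_model"
  )
}

# A group's weight in its parent: the max-Youden relevance of its training
# scores, i.e. the group is treated exactly as a continuous factor would be.
group_relevance <- function(scores, y, label) {
  sc <- scores[!is.na(scores)]
  yy <- y[!is.na(scores)]
  if (length(unique(yy)) < 2L) {
    warning("group '", label,
            "': one class has no non-missing training values; relevance set to 0",
            call. = FALSE)
    return(0)
  }
  youden_sweep(sc[yy == 1], sc[yy == 0])$relevance
}

#' @export
print.dsi_model <- function(x, ...) {
  cat("Disease State Index model:", length(x$groups), "group(s),",
      sum(x$training_summary$level == "factor"), "factor(s)\n")
  print(x$training_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Score subjects with a fitted Disease State Index model
#'
#' Evaluates every leaf fitness for each record, aggregates within groups and
#' then across groups by relevance-weighted averaging.  Missing values simply
#' drop out of the averages; a subject's index is missing only when every
#' leaf value is missing.  Extra columns in `newdata` are ignored.
#'
#' @param model A `dsi_model`.
#' @param newdata Data frame of subject records.
#' @param nodes If `TRUE`, return per-node scores (leaves and groups) along
#'   with the total.
#' @return If `nodes = FALSE` (default) a numeric vector of index values in
#'   `[0, 1]`; otherwise a list with `total`, `groups` (matrix) and `leaves`
#'   (matrix).
#' @export
score <- function(model, newdata, nodes = FALSE) {
  stopifnot(inherits(model, "dsi_model"))
  n <- nrow(newdata)
  group_scores <- matrix(NA_real_, n, length(model$groups),
                         dimnames = list(NULL, names(model$groups)))
  leaf_list <- list()
  for (g in names(model$groups)) {
    grp <- model$groups[[g]]
    leaf_fit <- matrix(NA_real_, n, length(grp$leaves),
                       dimnames = list(NULL, names(grp$leaves)))
    for (v in names(grp$leaves)) {
      vals <- if (v %in% names(newdata)) newdata[[v]] else rep(NA, n)
      leaf_fit[, v] <- fitness_value(grp$leaves[[v]], vals)
    }
    rel <- vapply(grp$leaves, `[[`, numeric(1), "relevance")
    group_scores[, g] <- aggregate_rows(leaf_fit, rel)
    leaf_list[[g]] <- leaf_fit
  }
  total <- aggregate_rows(group_scores, model$group_relevance)
  if (!nodes) return(total)
  list(total = total, groups = group_scores, leaves = do.call(cbind, leaf_list))
}

#' @export
predict.dsi_model <- function(object, newdata, ...) score(object, newdata)

#' Serialize a Disease State Index model to JSON
#'
#' The document contains the hierarchy, per-leaf support/fitness arrays,
#' orientations and relevances; [dsi_model_from_json()] restores an
#' equivalent model (round-trip stable).
#'
#' @param model A `dsi_model`.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
dsi_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "dsi_model"))
  doc <- list(
    format = "dsi_model",
    version = 1L,
    outcome_col = model$outcome_col,
    groups = lapply(model$groups, function(grp) {
      list(
        name = grp$name,
        relevance = grp$relevance,
        leaves = lapply(grp$leaves, function(lf) {
          list(variable = lf$variable, kind = lf$kind, group = lf$group,
               support = lf$support, categories = lf$categories,
               fitness = lf$fitness, relevance = lf$relevance,
               orientation = lf$orientation)
        })
      )
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Restore a Disease State Index model from JSON
#'
#' @param x A JSON string or path to a file written by [dsi_model_to_json()].
#' @return A `dsi_model`.
#' @export
dsi_model_from_json <- function(x) {
  doc <- if (length(x) == 1L && file.exists(x)) {
    jsonlite::read_json(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (!identical(doc$format, "dsi_model")) {
    stop("not a serialized dsi_model document", call. = FALSE)
  }
  groups <- lapply(doc$groups, function(grp) {
    leaves <- lapply(grp$leaves, function(lf) {
      structure(
        list(variable = lf$variable, kind = lf$kind, group = lf$group,
             support = if (!is.null(lf$support)) as.numeric(lf$support),
             categories = if (!is.null(lf$categories)) as.character(lf$categories),
             fitness = as.numeric(lf$fitness),
             relevance = as.numeric(lf$relevance),
             orientation = lf$orientation),
        class = "dsi_factor"
      )
    })
    names(leaves) <- vapply(leaves, `[[`, character(1), "variable")
    list(name = grp$name, leaves = leaves, relevance = as.numeric(grp$relevance))
  })
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  group_rel <- vapply(groups, `[[`, numeric(1), "relevance")
  summary_df <- do.call(rbind, lapply(names(groups), function(g) {
    rbind(
      data.frame(node = g, level = "group", group = g,
                 relevance = group_rel[[g]], stringsAsFactors = FALSE),
      data.frame(
        node = names(groups[[g]]$leaves), level = "factor", group = g,
        relevance = vapply(groups[[g]]$leaves, `[[`, numeric(1), "relevance"),
        stringsAsFactors = FALSE
      )
    )
  }))
  rownames(summary_df) <- NULL
  structure(
    list(groups = groups, group_relevance = group_rel,
         training_summary = summary_df,
         outcome_col = doc$outcome_col %||% "outcome"),
    class = "dsi_model"
  )
}
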