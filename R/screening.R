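# Univariate factor screening: only factors differing between outcome groups
# at p < alpha enter the index model.  Continuous/ordinal factors use the
# Mann-Whitney U test, binary/categorical factors the chi-square test.

#' Two-sided Mann-Whitney U test p-value
#'
#' Exact enumeration of all rank assignments when the combined sample size is
#' at most 10 (valid with ties, using midranks); tie-corrected normal
#' approximation otherwise.
#'
#' @param values_cases,values_controls Numeric vectors; missing values are
#'   dropped.
#' @return Two-sided p-value.
#' @export
#' @examples
#' mann_whitney_p(c(1, 2, 3), c(4, 5, 6))  # exact: 2/20
mann_whitney_p <- function(values_cases, values_controls) {
  x <- values_cases[!is.na(values_cases)]
  y <- values_controls[!is.na(values_controls)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups need at least one non-missing value", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  if (nx + ny <= 10L) {
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    combs <- utils::combn(nx + ny, nx)
    us <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
}

#' Pearson chi-square test p-value for a contingency table
#'
#' No continuity correction is applied.  Rows and columns with zero marginal
#' totals are dropped first; a table degenerate after dropping (fewer than two
#' rows or columns) gives p = 1 with a warning.
#'
#' @param table Matrix of non-negative counts.
#' @return Two-sided p-value.
#' @export
chi_square_p <- function(table) {
  tab <- as.matrix(table)
  if (any(is.na(tab)) || any(tab < 0)) {
    stop("contingency table must contain non-negative counts", call. = FALSE)
  }
  if (sum(tab) == 0) stop("contingency table has zero total", call. = FALSE)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate contingency table; p set to 1", call. = FALSE)
    return(1)
  }
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Screen factors against the outcome
#'
#' Applies the per-kind univariate test to every hierarchy variable and marks
#' it selected when `p < alpha` (strict).  A variable with a `screen_with`
#' reference inherits the p-value of the referenced variable's test, so a
#' family of derived binaries is covered by one test on the parent factor.
#' Variables whose test fails (e.g. one class entirely missing) are recorded
#' unselected with the failure reason.
#'
#' @param cohort Cohort data frame with a 0/1 `outcome` column.
#' @param hierarchy A `dsi_hierarchy` (or list of [variable_spec()]).
#' @param alpha Significance threshold (default 0.05).
#' @param outcome_col Outcome column name.
#' @return A `dsi_screening` data frame with columns `variable`, `group`,
#'   `kind`, `test`, `p_value`, `selected`, `reason`.
#' @export
screen_factors <- function(cohort, hierarchy, alpha = 0.05,
                           outcome_col = "outcome") {
  specs <- if (inherits(hierarchy, "dsi_hierarchy")) {
    hierarchy_specs(hierarchy)
  } else {
    hierarchy
  }
  y <- cohort[[outcome_col]]
  if (is.null(y) || any(is.na(y))) {
    stop("outcome must be present (non-missing) for all screened subjects",
         call. = FALSE)
  }
  one_test <- function(sp) {
    vals <- cohort[[sp$name]]
    if (is.null(vals)) {
      return(list(test = NA_character_, p = NA_real_, reason = "column absent"))
    }
    res <- tryCatch({
      if (sp$kind %in% c("continuous", "ordinal")) {
        list(test = "mann_whitney",
             p = mann_whitney_p(vals[y == 1], vals[y == 0]), reason = NA_character_)
      } else {
        tab <- table(factor(vals), factor(y, levels = c(0, 1)))
        list(test = "chi_square",
             p = suppressWarnings(chi_square_p(tab)), reason = NA_character_)
      }
    }, error = function(e) {
      list(test = NA_character_, p = NA_real_, reason = conditionMessage(e))
    })
    res
  }
  nms <- vapply(specs, `[[`, character(1), "name")
  prim <- lapply(specs, function(sp) if (is.null(sp$screen_with)) one_test(sp))
  names(prim) <- nms
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    if (is.null(sp$screen_with)) {
      r <- prim[[i]]
    } else {
      src <- prim[[sp$screen_with]]
      if (is.null(src)) {
        r <- list(test = NA_character_, p = NA_real_,
                  reason = paste0("screen_with target '", sp$screen_with,
                                  "' not screened"))
      } else {
        r <- list(test = paste0("inherited:", sp$screen_with), p = src$p,
                  reason = src$reason)
      }
    }
    data.frame(variable = sp$name, group = sp$group, kind = sp$kind,
               test = r$test, p_value = r$p,
               selected = !is.na(r$p) & r$p < alpha,
               reason = r$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("dsi_screening", "data.frame"), alpha = alpha)
}

#' Prune a hierarchy to its screened-in factors
#'
#' Removes unselected variables; groups left without any selected member are
#' pruned entirely.
#'
#' @param hierarchy A `dsi_hierarchy`.
#' @param screening A `dsi_screening` from [screen_factors()].
#' @return A `dsi_hierarchy` (possibly with zero groups).
#' @export
prune_hierarchy <- function(hierarchy, screening) {
  stopifnot(inherits(hierarchy, "dsi_hierarchy"))
  keep <- screening$variable[screening$selected]
  specs <- Filter(function(sp) sp$name %in% keep, hierarchy_specs(hierarchy))
  if (length(specs) == 0L) {
    return(structure(list(), class = "dsi_hierarchy"))
  }
  dsi_hierarchy(specs)
}
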