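#' Declare a model variable
#'
#' A variable spec states how one predictor is measured (its kind) and which
#' concept group it belongs to in the two-level model hierarchy (for example
#' all cognitive tests form one "cognition" group that is aggregated before
#' entering the total index).
#'
#' @param name Variable name; must match a cohort column.
#' @param kind One of `"continuous"`, `"ordinal"`, `"binary"`, `"categorical"`.
#' @param group Concept-group name (non-empty).
#' @param screen_with Optional name of another variable whose univariate
#'   screening p-value this variable inherits.  Used for binaries derived from
#'   a categorical parent (e.g. APOE carrier indicators inherit the genotype
#'   table's chi-square test) so that one statistical test covers the family.
#' @param direction_hint Optional `"cases_high"`/`"cases_low"` hint; by default
#'   orientation is learned from the data at fit time.
#' @return An object of class `dsi_varspec`.
#' @export
#' @examples
#' variable_spec("mmse_total", "ordinal", "cognition")
variable_spec <- function(name, kind, group,
                          screen_with = NULL, direction_hint = NULL) {
  kind <- match.arg(kind, c("continuous", "ordinal", "binary", "categorical"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.character(group) || length(group) != 1L || !nzchar(group)) {
    stop("`group` must be a non-empty string", call. = FALSE)
  }
  if (!is.null(direction_hint)) {
    direction_hint <- match.arg(direction_hint, c("cases_high", "cases_low"))
  }
  structure(
    list(name = name, kind = kind, group = group,
         screen_with = screen_with, direction_hint = direction_hint),
    class = "dsi_varspec"
  )
}

#' Build a two-level model hierarchy from variable specs
#'
#' @param specs List of [variable_spec()] objects; groups are taken from each
#'   spec's `group` field and ordered by first appearance.
#' @return An object of class `dsi_hierarchy`: a named list of groups, each a
#'   list of member specs.
#' @export
dsi_hierarchy <- function(specs) {
  if (length(specs) == 0L) stop("hierarchy must contain at least one variable", call. = FALSE)
  if (inherits(specs, "dsi_varspec")) specs <- list(specs)
  ok <- vapply(specs, inherits, logical(1), "dsi_varspec")
  if (!all(ok)) stop("all elements must be variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate variable names in hierarchy: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  groups <- vapply(specs, `[[`, character(1), "group")
  out <- lapply(unique(groups), function(g) {
    list(name = g, variables = specs[groups == g])
  })
  names(out) <- unique(groups)
  structure(out, class = "dsi_hierarchy")
}

#' @export
print.dsi_hierarchy <- function(x, ...) {
  cat("DSI hierarchy:", length(x), "groups,",
      length(hierarchy_specs(x)), "variables\n")
  for (g in x) {
    cat("  ", g$name, ": ",
        paste(vapply(g$variables, `[[`, character(1), "name"), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Flatten a hierarchy to its variable specs
#' @param hierarchy A `dsi_hierarchy`.
#' @return Unnamed list of `dsi_varspec` objects in hierarchy order.
#' @export
hierarchy_specs <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "dsi_hierarchy"))
  unlist(lapply(hierarchy, `[[`, "variables"), recursive = FALSE)
}

#' Read a hierarchy configuration from YAML or JSON
#'
#' The file holds a top-level `groups` list; each group has a `name` and a
#' `variables` list of `{name, kind}` entries (`screen_with` optional).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `dsi_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$groups)) stop("config must have a top-level `groups` list", call. = FALSE)
  specs <- list()
  for (g in cfg$groups) {
    if (is.null(g$name)) stop("every group needs a `name`", call. = FALSE)
    for (v in g$variables) {
      specs[[length(specs) + 1L]] <- variable_spec(
        name = v$name, kind = v$kind, group = g$name,
        screen_with = v$screen_with %||% NULL
      )
    }
  }
  dsi_hierarchy(specs)
}

aux_columns <- c("follow_up_years", "died_within_2y",
                 "autopsy_available", "baseline_dementia")

coerce_variable <- function(x, spec) {
  n_bad <- 0L
  if (spec$kind %in% c("continuous", "ordinal", "binary")) {
    suppressWarnings(v <- as.numeric(as.character(x)))
    n_bad <- sum(!is.na(x) & x != "" & is.na(v))
    if (spec$kind == "binary") {
      bad <- !is.na(v) & !(v %in% c(0, 1))
      n_bad <- n_bad + sum(bad)
      v[bad] <- NA_real_
    }
  } else {
    v <- as.character(x)
    v[!is.na(v) & v == ""] <- NA_character_
  }
  list(value = v, n_bad = n_bad)
}

#' Read a cohort table
#'
#' Reads a delimited text file with a header row, one subject per row, and
#' coerces each declared variable to its spec kind.  Cells equal to
#' `missing_token` (and, for numeric kinds, unparseable cells) become `NA`;
#' the number of unparseable cells is reported as a warning and stored in the
#' `n_warnings` attribute.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param specs A `dsi_hierarchy` or list of [variable_spec()] objects.
#' @param missing_token String encoding a missing cell (default empty string).
#' @param sep Field separator (default `","`).
#' @return A `dsi_cohort` data frame with columns `subject_id`, `outcome`
#'   (0/1/`NA`), any auxiliary flag columns present in the file, and one column
#'   per declared variable.
#' @export
read_cohort <- function(path, specs, missing_token = "", sep = ",") {
  if (inherits(specs, "dsi_hierarchy")) specs <- hierarchy_specs(specs)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = missing_token, quote = "\"",
                           comment.char = "", encoding = "UTF-8")
  spec_names <- vapply(specs, `[[`, character(1), "name")
  known <- c("subject_id", "outcome", aux_columns, spec_names)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown column(s) not in variable specs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"subject_id" %in% names(raw)) stop("cohort file needs a subject_id column", call. = FALSE)
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject_id values: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(subject_id = as.character(raw$subject_id),
                    stringsAsFactors = FALSE)
  if ("outcome" %in% names(raw)) {
    suppressWarnings(oc <- as.numeric(raw$outcome))
    if (any(!is.na(oc) & !(oc %in% c(0, 1)))) {
      stop("outcome must be 0/1 or missing", call. = FALSE)
    }
    out$outcome <- oc
  }
  for (ac in intersect(aux_columns, names(raw))) {
    if (ac == "follow_up_years") {
      suppressWarnings(out[[ac]] <- as.numeric(raw[[ac]]))
    } else {
      v <- as.logical(raw[[ac]])  # TRUE/FALSE/T/F strings
      num <- suppressWarnings(as.numeric(raw[[ac]]))
      v[is.na(v)] <- num[is.na(v)] != 0  # 0/1 encoding
      out[[ac]] <- v
    }
  }
  n_warn <- 0L
  for (sp in specs) {
    if (!sp$name %in% names(raw)) next
    cv <- coerce_variable(raw[[sp$name]], sp)
    out[[sp$name]] <- cv$value
    n_warn <- n_warn + cv$n_bad
  }
  if (n_warn > 0L) {
    warning(sprintf("%d cell(s) could not be parsed and were set to missing", n_warn),
            call. = FALSE)
  }
  as_dsi_cohort(out, specs, n_warnings = n_warn)
}

as_dsi_cohort <- function(df, specs, n_warnings = 0L) {
  structure(df,
            class = c("dsi_cohort", "data.frame"),
            specs = specs, n_warnings = n_warnings)
}

#' Validate an in-memory cohort against its variable specs
#'
#' @param cohort A data frame or `dsi_cohort`.
#' @param specs A `dsi_hierarchy` or list of variable specs.
#' @return Invisibly, a list with `ok` (logical) and `problems` (character
#'   vector); problems also raise warnings.
#' @export
validate_cohort <- function(cohort, specs) {
  if (inherits(specs, "dsi_hierarchy")) specs <- hierarchy_specs(specs)
  probs <- character()
  if (!"subject_id" %in% names(cohort)) probs <- c(probs, "missing subject_id column")
  else if (anyDuplicated(cohort$subject_id)) probs <- c(probs, "duplicate subject_id")
  if ("outcome" %in% names(cohort) && !is_binary01(cohort$outcome)) {
    probs <- c(probs, "outcome not coded 0/1")
  }
  for (sp in specs) {
    if (!sp$name %in% names(cohort)) {
      probs <- c(probs, paste0("missing variable column: ", sp$name))
      next
    }
    x <- cohort[[sp$name]]
    if (sp$kind %in% c("continuous", "ordinal")) {
      if (!is.numeric(x)) probs <- c(probs, paste0(sp$name, ": not numeric"))
    } else if (sp$kind == "binary") {
      if (!is_binary01(x)) probs <- c(probs, paste0(sp$name, ": not 0/1"))
    }
  }
  for (p in probs) warning(p, call. = FALSE)
  invisible(list(ok = length(probs) == 0L, problems = probs))
}

#' Apply the study inclusion filters
#'
#' The dementia model excludes subjects with baseline dementia and subjects
#' who died within the first two years of follow-up (to remove mortality-driven
#' differences); the pathology model excludes baseline dementia and subjects
#' without autopsy data.
#'
#' @param cohort A `dsi_cohort` with the relevant auxiliary flag columns.
#' @param model_kind `"dementia"` or `"pathology"`.
#' @return The filtered cohort; the named exclusion tally is stored in the
#'   `exclusions` attribute.
#' @export
apply_inclusion_filters <- function(cohort, model_kind = c("dementia", "pathology")) {
  model_kind <- match.arg(model_kind)
  need <- if (model_kind == "dementia") {
    c("baseline_dementia", "died_within_2y")
  } else {
    c("baseline_dementia", "autopsy_available")
  }
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("missing auxiliary flag column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bd <- isTRUE_vec(cohort$baseline_dementia)
  excl <- c(baseline_dementia = sum(bd))
  keep <- !bd
  if (model_kind == "dementia") {
    dw <- isTRUE_vec(cohort$died_within_2y)
    excl <- c(excl, died_within_2y = sum(dw & keep))
    keep <- keep & !dw
  } else {
    na_flag <- !isTRUE_vec(cohort$autopsy_available)
    excl <- c(excl, no_autopsy = sum(na_flag & keep))
    keep <- keep & !na_flag
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = class(cohort),
            specs = attr(cohort, "specs"),
            n_warnings = attr(cohort, "n_warnings"),
            exclusions = excl)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

apoe_genotypes <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")

normalize_apoe <- function(genotype) {
  g <- gsub("ε", "e", as.character(genotype))  # accept epsilon glyphs
  g <- tolower(gsub("[ /]", "", g))
  bad <- !is.na(g) & !(g %in% apoe_genotypes)
  if (any(bad)) {
    stop("unknown APOE genotype value(s): ",
         paste(unique(genotype[bad]), collapse = ", "), call. = FALSE)
  }
  g
}

#' Derive APOE carrier factors from genotype
#'
#' Expands the six-level APOE genotype into the three binary factors used as
#' individual predictors (epsilon-2 carrier, epsilon-4 carrier, epsilon-3/3
#' homozygote) plus the normalized categorical genotype itself.  Missing
#' genotype propagates to all derived values.
#'
#' @param genotype Character vector with values among
#'   `"e2e2","e2e3","e2e4","e3e3","e3e4","e4e4"` (epsilon glyphs accepted).
#' @return A data frame with columns `apoe_e2_carrier`, `apoe_e4_carrier`,
#'   `apoe_e3e3` (each 0/1/`NA`) and `apoe_genotype`.
#' @export
#' @examples
#' derive_apoe_factors(c("e2e4", "e3e3", NA))
derive_apoe_factors <- function(genotype) {
  g <- normalize_apoe(genotype)
  data.frame(
    apoe_e2_carrier = ifelse(is.na(g), NA_real_, as.numeric(grepl("e2", g))),
    apoe_e4_carrier = ifelse(is.na(g), NA_real_, as.numeric(grepl("e4", g))),
    apoe_e3e3 = ifelse(is.na(g), NA_real_, as.numeric(g == "e3e3")),
    apoe_genotype = g,
    stringsAsFactors = FALSE
  )
}
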