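# Neuropathology outcomes: dichotomization of raw pathology measures,
# the NIA-AA Braak-by-CERAD likelihood lookup, and the centered (unscaled)
# principal-component stage whose scores are assessed as dementia predictors.

braak_levels <- c("0", "I", "II", "III", "IV", "V", "VI")
cerad_levels <- c("none", "sparse", "moderate", "frequent")

#' Default NIA-AA likelihood lookup matrix
#'
#' Braak-stage groups (0-II, III-IV, V-VI) by CERAD neuritic-plaque score.
#' High likelihood: Braak V-VI with moderate/frequent plaques; intermediate:
#' Braak III-IV with moderate/frequent, or Braak V-VI with sparse; all other
#' combinations low.  The matrix is plain data and can be replaced wholesale
#' through the `mapping` argument of [niaaa_likelihood()].
#'
#' @return A 3 x 4 character matrix with rownames `"0-II"`, `"III-IV"`,
#'   `"V-VI"` and colnames the CERAD scores.
#' @export
default_niaaa_matrix <- function() {
  m <- matrix("low", 3, 4,
              dimnames = list(c("0-II", "III-IV", "V-VI"), cerad_levels))
  m["III-IV", c("moderate", "frequent")] <- "intermediate"
  m["V-VI", "sparse"] <- "intermediate"
  m["V-VI", c("moderate", "frequent")] <- "high"
  m
}

braak_group <- function(braak) {
  b <- as.character(braak)
  b[b %in% as.character(0:6)] <- braak_levels[match(b[b %in% as.character(0:6)],
                                                    as.character(0:6))]
  bad <- !is.na(b) & !(b %in% braak_levels)
  if (any(bad)) {
    stop("Braak stage outside 0/I-VI: ", paste(unique(b[bad]), collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_character_, length(b))
  out[b %in% c("0", "I", "II")] <- "0-II"
  out[b %in% c("III", "IV")] <- "III-IV"
  out[b %in% c("V", "VI")] <- "V-VI"
  out
}

#' NIA-AA likelihood of Alzheimer's disease from Braak and CERAD
#'
#' Looks up the likelihood category in a configurable Braak-group by
#' CERAD-score matrix (default [default_niaaa_matrix()]).  Vectorized;
#' missing stages give a missing likelihood.
#'
#' @param braak Braak stage: `"0"`, `"I"` ... `"VI"` (integers 0-6 accepted).
#' @param cerad CERAD score: `"none"`, `"sparse"`, `"moderate"`, `"frequent"`.
#' @param mapping Likelihood lookup matrix.
#' @return Character vector with values `"low"`, `"intermediate"`, `"high"`.
#' @export
#' @examples
#' niaaa_likelihood("VI", "frequent")  # "high"
niaaa_likelihood <- function(braak, cerad, mapping = default_niaaa_matrix()) {
  bg <- braak_group(braak)
  cd <- as.character(cerad)
  bad <- !is.na(cd) & !(cd %in% cerad_levels)
  if (any(bad)) {
    stop("CERAD score outside enumeration: ",
         paste(unique(cd[bad]), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(bg))
  ok <- !is.na(bg) & !is.na(cd)
  out[ok] <- mapping[cbind(bg[ok], cd[ok])]
  out
}

pathology_outcomes <- c("amyloid", "tangles", "neuropath_ad", "caa",
                        "macroinfarcts", "cortical_macroinfarcts",
                        "wm_macroinfarcts", "microinfarcts",
                        "alpha_synuclein", "hs", "tdp43")

check_count <- function(x, name, integral = TRUE) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) stop(name, " must be non-negative", call. = FALSE)
  if (integral) {
    ni <- !is.na(x) & x != round(x)
    if (any(ni)) stop(name, " must be integral counts", call. = FALSE)
  }
  x
}

#' Derive the binary neuropathological outcome panel
#'
#' Dichotomizes each raw pathology measure as present versus absent:
#' strictly positive quantitative loads/counts are present (amyloid load,
#' tangle count, CAA percentage, macro-/cortical/white-matter/microinfarct
#' counts); alpha-synuclein is present for brainstem, limbic or diffuse
#' neocortical pathology; hippocampal sclerosis for severe marked/total
#' neuronal loss; TDP-43 as its immunopositivity flag; and neuropathological
#' AD when the NIA-AA likelihood from Braak and CERAD is intermediate or
#' high.  A missing input yields a missing value for that outcome only.
#'
#' @param panel Data frame with any of the columns `amyloid_load`,
#'   `tangle_count`, `caa_percent`, `macroinfarct_count`,
#'   `cortical_macroinfarct_count`, `wm_macroinfarct_count`,
#'   `microinfarct_count`, `alpha_synuclein`, `hs_severity`,
#'   `tdp43_positive`, `braak_stage`, `cerad_score`.
#' @param mapping NIA-AA lookup matrix for [niaaa_likelihood()].
#' @return The input with appended columns `outcome_<name>` in
#'   `{0, 1, NA}` for each derivable outcome.
#' @export
derive_outcomes <- function(panel, mapping = default_niaaa_matrix()) {
  n <- nrow(panel)
  col <- function(nm) if (nm %in% names(panel)) panel[[nm]] else rep(NA, n)
  gt0 <- function(x) ifelse(is.na(x), NA_real_, as.numeric(x > 0))
  out <- panel
  out$outcome_amyloid <- gt0(check_count(col("amyloid_load"), "amyloid_load",
                                         integral = FALSE))
  out$outcome_tangles <- gt0(check_count(col("tangle_count"), "tangle_count",
                                         integral = FALSE))
  out$outcome_caa <- gt0(check_count(col("caa_percent"), "caa_percent",
                                     integral = FALSE))
  out$outcome_macroinfarcts <- gt0(check_count(col("macroinfarct_count"),
                                               "macroinfarct_count"))
  out$outcome_cortical_macroinfarcts <-
    gt0(check_count(col("cortical_macroinfarct_count"),
                    "cortical_macroinfarct_count"))
  out$outcome_wm_macroinfarcts <-
    gt0(check_count(col("wm_macroinfarct_count"), "wm_macroinfarct_count"))
  out$outcome_microinfarcts <- gt0(check_count(col("microinfarct_count"),
                                               "microinfarct_count"))
  asyn <- as.character(col("alpha_synuclein"))
  bad <- !is.na(asyn) &
    !(asyn %in% c("absent", "brainstem", "limbic", "diffuse_neocortical"))
  if (any(bad)) {
    stop("alpha_synuclein outside enumeration: ",
         paste(unique(asyn[bad]), collapse = ", "), call. = FALSE)
  }
  out$outcome_alpha_synuclein <- ifelse(is.na(asyn), NA_real_,
                                        as.numeric(asyn != "absent"))
  hs <- as.character(col("hs_severity"))
  badh <- !is.na(hs) & !(hs %in% c("no_minor", "severe_marked_total"))
  if (any(badh)) {
    stop("hs_severity outside enumeration: ",
         paste(unique(hs[badh]), collapse = ", "), call. = FALSE)
  }
  out$outcome_hs <- ifelse(is.na(hs), NA_real_,
                           as.numeric(hs == "severe_marked_total"))
  tdp <- col("tdp43_positive")
  out$outcome_tdp43 <- ifelse(is.na(tdp), NA_real_, as.numeric(as.logical(tdp)))
  lik <- niaaa_likelihood(col("braak_stage"), col("cerad_score"), mapping)
  out$outcome_neuropath_ad <- ifelse(is.na(lik), NA_real_,
                                     as.numeric(lik %in% c("intermediate", "high")))
  out
}

#' Centered principal component analysis of a pathology matrix
#'
#' Columns are centered but not scaled (variables keep their natural
#' variances).  Rows with any missing value are dropped first and the count
#' reported.  Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x Numeric matrix or data frame, subjects in rows, pathology
#'   variables in columns.
#' @param n_components Number of components to retain (default: all).
#' @return A `dsi_pca` list: `loadings` (variables x components), `scores`
#'   (kept subjects x components, zero column means), `variance_explained`
#'   (all components; sums to 1), `center`, `kept_rows` (row indices of
#'   complete cases), `n_dropped`.
#' @export
run_pca <- function(x, n_components = NULL) {
  mat <- as.matrix(x)
  storage.mode(mat) <- "double"
  cc <- stats::complete.cases(mat)
  n_dropped <- sum(!cc)
  mat <- mat[cc, , drop = FALSE]
  if (nrow(mat) < 2L) stop("need at least 2 complete rows for PCA", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation
  sco <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (!is.null(n_components)) {
    n_components <- min(n_components, ncol(rot))
    rot <- rot[, seq_len(n_components), drop = FALSE]
    sco <- sco[, seq_len(n_components), drop = FALSE]
  }
  structure(
    list(loadings = rot, scores = sco, variance_explained = ve,
         center = pc$center, kept_rows = which(cc), n_dropped = n_dropped),
    class = "dsi_pca"
  )
}

#' @export
print.dsi_pca <- function(x, ...) {
  cat(sprintf("Centered PCA: %d subjects (%d dropped), %d variables\n",
              nrow(x$scores), x$n_dropped, nrow(x$loadings)))
  cat("Variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Assess principal-component scores as dementia predictors
#'
#' Computes the rank-based AUC of each retained component's subject scores
#' against the dementia labels.  Components discriminating in the opposite
#' direction (AUC below 0.5) are flagged and additionally reported with
#' orientation-corrected AUC.
#'
#' @param pca A `dsi_pca` from [run_pca()].
#' @param dementia_labels 0/1 labels aligned with the complete-case rows kept
#'   by the PCA.
#' @return Data frame with columns `component`, `variance_explained`, `auc`,
#'   `inverted`, `auc_oriented`.
#' @export
pc_dementia_auc <- function(pca, dementia_labels) {
  stopifnot(inherits(pca, "dsi_pca"))
  if (length(dementia_labels) != nrow(pca$scores)) {
    stop("labels must align with the PCA's retained complete-case rows",
         call. = FALSE)
  }
  if (length(unique(dementia_labels[!is.na(dementia_labels)])) < 2L) {
    stop("dementia labels contain a single class", call. = FALSE)
  }
  aucs <- vapply(seq_len(ncol(pca$scores)), function(j) {
    auc(pca$scores[, j], dementia_labels)
  }, numeric(1))
  data.frame(
    component = colnames(pca$scores),
    variance_explained = pca$variance_explained[seq_len(ncol(pca$scores))],
    auc = aucs,
    inverted = aucs < 0.5,
    auc_oriented = pmax(aucs, 1 - aucs),
    stringsAsFactors = FALSE
  )
}
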