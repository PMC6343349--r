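# Independent oracles used to cross-check the package implementation.

# Brute-force maximum Youden index: explicit confusion-matrix counting over
# every observed threshold and both orientations.
oracle_relevance <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls)))
  best <- 0
  for (t in thr) {
    # orientation A: predict case iff value >= t
    tp <- sum(cases >= t); fn <- sum(cases < t)
    tn <- sum(controls < t); fp <- sum(controls >= t)
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
    # orientation B: predict case iff value <= t
    tp <- sum(cases <= t); fn <- sum(cases > t)
    tn <- sum(controls > t); fp <- sum(controls <= t)
    best <- max(best, tp / (tp + fn) + tn / (tn + fp) - 1)
  }
  best
}

# Pairwise win-fraction AUC: enumerate every case-control pair.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  wins <- 0
  for (a in cs) for (b in ct) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(cs) * length(ct))
}

# PCA via explicit eigendecomposition of the centered covariance matrix.
oracle_pca <- function(x) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  scores <- xc %*% ev$vectors
  list(values = ev$values, vectors = ev$vectors, scores = scores)
}

# All multisets of the given size drawn from a value grid.
multisets <- function(grid, size) {
  cmb <- utils::combn(length(grid) + size - 1, size)
  apply(cmb, 2, function(idx) grid[idx - seq_len(size) + 1], simplify = FALSE)
}

# A tiny two-group cohort + hierarchy for structural tests.
tiny_hierarchy <- function() {
  dsi_hierarchy(list(
    variable_spec("a1", "continuous", "ga"),
    variable_spec("a2", "continuous", "ga"),
    variable_spec("b1", "continuous", "gb")
  ))
}

tiny_cohort <- function(seed = 1, n = 40, sep = c(a1 = 2, a2 = 1, b1 = 0)) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  data.frame(
    subject_id = paste0("s", seq_len(n)),
    outcome = y,
    a1 = rnorm(n) + sep[["a1"]] * y,
    a2 = rnorm(n) + sep[["a2"]] * y,
    b1 = rnorm(n) + sep[["b1"]] * y,
    stringsAsFactors = FALSE
  )
}
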