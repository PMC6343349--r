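# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so package functions never clobber user RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

# Sample from a normal distribution truncated to [lower, upper] by inverse-CDF.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate distribution outside truncation bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop(sprintf(
      "infeasible truncation: [%g, %g] has no mass under N(%g, %g)",
      lower, upper, mean, sd
    ), call. = FALSE)
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# md5 of a canonical JSON rendering, used for provenance records
json_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
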