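# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user scripts.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-task seed from a master seed; stays within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

# Validation helpers: fail with the offending field named.
check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %s", field, min), call. = FALSE)
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a number in [%s, %s]", field, min, max),
         call. = FALSE)
  }
  as.double(x)
}

check_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("'%s' must be a non-empty string", field), call. = FALSE)
  }
  x
}

# p-value from a null sample using the add-one estimator (never zero).
pval_from_null <- function(null, observed,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(null)
  p_greater <- (1 + sum(null >= observed)) / (1 + n)
  p_less <- (1 + sum(null <= observed)) / (1 + n)
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  list(p = p, p_greater = p_greater, p_less = p_less)
}

# Deterministic TSV writer used for all output tables.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
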