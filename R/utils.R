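# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded sub-computations do not
#' perturb the caller's RNG stream.
#' @noRd
.withSeed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# derive a child seed from a master seed and a stage offset, kept inside
# 32-bit integer range
.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483587L)
}

# deterministic integer from a character key (for subset-derived seeds)
.stringSeed <- function(key) {
  codes <- utf8ToInt(paste(key, collapse = "|"))
  h <- 5381
  for (k in codes) h <- (h * 33 + k) %% 2147483587
  as.integer(h)
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# average ranks (midranks) of a numeric vector
.midrank <- function(x) rank(x, ties.method = "average")
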