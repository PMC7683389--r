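# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named sub-stream seed from a master seed
#'
#' One master seed fans out to independent named sub-streams (labeled-subset
#' draw, per-tree candidate generation, bootstrap resampling, ...) so that
#' stochastic components can be perturbed independently while every run stays
#' reproducible from a single integer.
#'
#' @param master Integer master seed.
#' @param ... Character or integer tags naming the sub-stream
#'   (e.g. `"tree"`, `7`).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "tree", 3)
#' @export
derive_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.double(master) %% 2147483647
  for (tag in tags) {
    codes <- if (is.character(tag)) utf8ToInt(tag) else as.integer(tag) + 1L
    for (cc in codes) {
      h <- (h * 31 + as.double(cc)) %% 2147483647
    }
    h <- (h * 131071 + 17) %% 2147483647
  }
  as.integer(h)
}

# argmax with lowest-index tie-breaking, rows of a matrix
row_argmax <- function(m) {
  max.col(m, ties.method = "first")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
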