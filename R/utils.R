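#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Keeps every stochastic operation seed-addressable without touching the
# global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# per-stage / per-object seeds so any stage can be re-run in isolation.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Binary-matrix coercion used across modules: accepts logical or numeric
# matrices (anything > 0 is foreground).
as_binary_matrix <- function(mask) {
  if (is.data.frame(mask)) mask <- as.matrix(mask)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mode(mask) <- "numeric"
  mask > 0
}
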