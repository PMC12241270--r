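#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats runif rnorm sd quantile predict
#' @importFrom utils head tail
NULL

# consistent error classes so the CLI can map them to exit codes
abort_config <- function(msg) abort(msg, class = "ppgbp_config_error")
abort_input  <- function(msg) abort(msg, class = "ppgbp_input_error")
abort_train  <- function(msg) abort(msg, class = "ppgbp_train_error")

# Derive a child seed from a base seed and a stream index; stays inside the
# 32-bit integer range so it is safe for set.seed() on any platform.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards (same contract as withr::with_seed).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

stopifnot_range <- function(r, what) {
  if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
    abort_config(sprintf("`%s` must be a finite numeric interval c(lo, hi) with lo <= hi.", what))
  }
}

# Stable content hash of an R object (used for config hashes / manifests).
config_hash <- function(x) rlang::hash(x)
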