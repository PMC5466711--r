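#' @keywords internal
"_PACKAGE"

## Run expr with a deterministic RNG state, restoring the caller's state after.
## Keeps package functions reproducible without clobbering the user's stream.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Small deterministic stream-seed derivation: combine a root seed with index
## integers into a 31-bit seed. Stable across platforms (pure integer arithmetic
## done in double precision, all values < 2^31).
derive_seed <- function(root, ...) {
  idx <- c(...)
  h <- as.double(root) %% 2147483647
  for (v in idx) {
    h <- (h * 48271 + as.double(v) + 11) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Canonical intrinsic connectivity network labels
#'
#' The seven canonical cortical networks plus a catch-all label for regions
#' that overlap none of them. Used as the fixed ordering for network-sorted
#' edge vectors.
#'
#' @return Character vector of eight network labels.
#' @export
canonical_networks <- function() {
  c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
    "limbic", "frontoparietal", "default", "no_overlap")
}
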