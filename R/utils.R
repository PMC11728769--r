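# Internal helpers: seeding, probability maps, hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so seeded
#' package functions never perturb the global random stream. A `NULL` seed
#' leaves the current stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  expr
}

#' Derive a stable sub-seed from a master seed and a label
#'
#' Splitting scheme for scenario batches: the sub-seed depends only on the
#' master seed and the label (not on position in a list), so adding a scenario
#' never perturbs another scenario's draws. Result is kept in [0, 2^31 - 2].
#' @noRd
derive_subseed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

#' Renormalize a named probability map
#'
#' Probabilities printed in source tables occasionally sum to slightly less
#' than 1 (rounding); maps are always renormalized to sum to exactly 1.
#' A notice is emitted when the raw sum is off by more than `notify_tol`.
#' @noRd
renormalize_probs <- function(probs, what = "probability map",
                              notify_tol = 1e-6) {
  if (length(probs) == 0L) {
    stop(sprintf("%s is empty", what), call. = FALSE)
  }
  p <- unlist(probs)
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(sprintf("%s must be a named vector or list", what), call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    bad <- names(p)[!is.finite(p) | p < 0][1L]
    stop(sprintf("%s: negative or non-finite probability for '%s'", what, bad),
         call. = FALSE)
  }
  s <- sum(p)
  if (s <= 0) {
    stop(sprintf("%s: probabilities sum to zero", what), call. = FALSE)
  }
  if (abs(s - 1) > notify_tol) {
    message(sprintf("%s summed to %.6g; renormalized to 1", what, s))
  }
  p / s
}

#' FNV-1a hash of a serialized R object, as an 8-hex-digit string
#' @noRd
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0x811c9dc5 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
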