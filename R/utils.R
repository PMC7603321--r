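# Internal helpers shared across modules.

#' @importFrom rlang %||%
NULL

# Derive a reproducible child seed from a root seed and an integer offset.
# Arithmetic stays below 2^53 so the double-precision modulus is exact,
# and the result fits a 32-bit R integer.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  v <- ((as.double(seed) %% 2147483647) * 48271 +
          9973 * (as.double(offset) %% 99991)) %% 2147483629
  as.integer(v)
}

# Stable small hash of a character id, for per-subject seed derivation.
id_hash <- function(id) {
  vapply(as.character(id), function(s) {
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 999983L
  }, integer(1), USE.NAMES = FALSE)
}

# Run `expr` under a temporary RNG state seeded by `seed`; if seed is NULL,
# use the ambient RNG stream unchanged.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

assert_square_symmetric <- function(w, what = "matrix") {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(w))) stop(what, " must have finite entries", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-8 * max(1, max(abs(w)))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(w)
}

upper_index <- function(n) which(upper.tri(matrix(0, n, n)))
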