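# Internal helpers: classed error conditions, combination-key arithmetic,
# and a local RNG scope so simulations never disturb the caller's stream.

abort_validation <- function(msg) {
  stop(errorCondition(msg,
                      class = c("qsarens_validation_error", "qsarens_error",
                                "error", "condition")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg,
                      class = c("qsarens_io_error", "qsarens_error",
                                "error", "condition")))
}

is_binary <- function(x) {
  !anyNA(x) && all(x == 0L | x == 1L)
}

# All 2^m prediction combinations in lexicographic bitstring order
# (0...00, 0...01, ..., 1...11); column j is the bit of tool j.
enumerate_keys <- function(m) {
  stopifnot(m >= 1)
  g <- as.matrix(expand.grid(rep(list(0:1), m), KEEP.OUT.ATTRS = FALSE))
  k <- g[, m:1, drop = FALSE]
  dimnames(k) <- NULL
  storage.mode(k) <- "integer"
  k
}

# 1-based row index of a key (or matrix of keys, one per row) in the
# lexicographic enumeration: bitstring read as a base-2 integer, plus 1.
key_index <- function(bits) {
  if (is.matrix(bits)) {
    m <- ncol(bits)
    as.integer(bits %*% 2^((m - 1):0)) + 1L
  } else {
    m <- length(bits)
    as.integer(sum(bits * 2^((m - 1):0))) + 1L
  }
}

key_string <- function(bits) {
  if (is.matrix(bits)) apply(bits, 1L, paste0, collapse = "")
  else paste0(bits, collapse = "")
}

check_key <- function(key, m) {
  key <- as.integer(key)
  if (length(key) != m)
    abort_validation(sprintf(
      "combination key has length %d but the decision table expects m = %d",
      length(key), m))
  if (!is_binary(key))
    abort_validation("combination key entries must all be 0 or 1")
  key
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
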