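#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble as_tibble
#' @importFrom stats rnorm runif setNames sd cor var predict
#' @importFrom utils head tail
NULL

#' @export
tibble::as_tibble

# Deterministic seed derivation: one root seed fans out to per-stage seeds so
# no stage consumes global randomness. Polynomial rolling hash of the label,
# folded with the root seed, kept below 2^31.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) * 7919 + h) %% 2147483629L + 1L)
}

# Run expr with a local RNG state seeded at `seed`; restores the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# numerically stable softplus and its inverse
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

check_row_stochastic <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    abort("regime transition matrix must be square")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > tol)) {
    abort("regime transition matrix must be row-stochastic (rows sum to 1)")
  }
  invisible(P)
}

# Adjusted Rand index between two labelings (used for embedding stability).
adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)
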