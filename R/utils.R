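# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so seeded package internals never disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically combine a base seed with substream indices, staying inside
# 32-bit integer range.
derive_seed <- function(base, ...) {
  parts <- c(as.numeric(base), as.numeric(c(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p) %% 2147483647
  as.integer(s)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

# column means / sds without matrixStats
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1L))
}
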