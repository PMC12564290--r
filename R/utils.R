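#' @importFrom rlang .data abort warn
#' @importFrom stats cor rnorm runif sd qnorm setNames
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib popconn, .registration = TRUE
NULL

# Lehmer-style fold of integer components into one 31-bit stream seed.
# Products stay below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  if (any(!is.finite(parts))) abort("seed components must be finite")
  m <- 2147483647
  s <- 11
  for (p in parts) {
    s <- (s * 48271 + (abs(p) %% m) + 1) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

# Evaluate expr under a local RNG state seeded from components; restores the
# caller's RNG so generation order elsewhere is unaffected.
with_stream <- function(..., expr) {
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
  set.seed(derive_seed(...))
  expr
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    abort(sprintf("`%s` = %s is out of range", name, format(x)))
  }
  as.numeric(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix", name))
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite entries", name))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
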