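#' @importFrom stats rnorm runif cov pnorm dnorm wilcox.test p.adjust sd
#' @importFrom utils modifyList head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## data.table is used through :: ; declare awareness so [.data.table
## semantics apply inside the package namespace.
.datatable.aware <- TRUE

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded draws inside the
#' package never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Deterministic derived seeds; kept well below 2^31.
derive_seed <- function(seed, ...) {
  ks <- as.numeric(c(seed, ...))
  h <- 0
  for (k in ks) h <- (h * 7919 + (k %% 104729)) %% 2147480009
  as.integer(h)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Snap intensities to the 16-bit grid used on disk, so that rendering,
## TIFF writing and reading are bit-identical.
quantize16 <- function(x) round(x * 65535) / 65535

is_square_sym <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Relative Frobenius distance between two matrices
#'
#' `||a - b||_F / ||b||_F` (plain Frobenius norm of the difference when
#' `b` is zero); the residual used to report second-moment matching.
#'
#' @param a,b matrices of equal dimension.
#' @return nonnegative scalar.
#' @export
rel_frobenius <- function(a, b) {
  denom <- sqrt(sum(b^2))
  if (denom == 0) return(sqrt(sum((a - b)^2)))
  sqrt(sum((a - b)^2)) / denom
}

## Draw n rows from N(0, Sigma) via eigendecomposition (tolerates a
## singular Sigma, unlike a Cholesky factor).
rmvnorm_eig <- function(n, sigma) {
  p <- nrow(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- matrix(rnorm(n * p), n, p)
  z %*% (t(e$vectors) * sqrt(vals))
}
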