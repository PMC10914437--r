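## Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

## small paired dataset (60 cells/class) used by most data-layer tests
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_default_config(n0 = 60, n1 = 60, seed = 101)
    .fixture_env$small <- simulate_dataset(cfg)
  }
  .fixture_env$small
}

## medium dataset (500 cells/class) for statistical properties
medium_dataset <- function() {
  if (is.null(.fixture_env$medium)) {
    cfg <- sim_default_config(n0 = 500, n1 = 500, seed = 202)
    .fixture_env$medium <- simulate_dataset(cfg)
  }
  .fixture_env$medium
}

## full study-scale dataset (2000 cells/class, the default conditions)
big_dataset <- function() {
  if (is.null(.fixture_env$big)) {
    .fixture_env$big <- simulate_dataset(sim_default_config(seed = 404))
  }
  .fixture_env$big
}

## written fixture directory for the small dataset
small_fixture_dir <- function() {
  if (is.null(.fixture_env$small_dir)) {
    d <- file.path(tempdir(), "stimedit-small-fixture")
    write_fixture(small_dataset(), d, overwrite = TRUE)
    .fixture_env$small_dir <- d
  }
  .fixture_env$small_dir
}

## random symmetric PSD matrix
random_psd <- function(p, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  crossprod(a) / p
}

## independent textbook SSIM: direct per-window double loop
reference_ssim <- function(x, y, data_range = 1, win = 11, sigma = 1.5,
                           k1 = 0.01, k2 = 0.03) {
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  wmat <- outer(g1, g1)
  wmat <- wmat / sum(wmat)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  h <- nrow(x); w <- ncol(x)
  vals <- c()
  for (i in 1:(h - win + 1)) {
    for (j in 1:(w - win + 1)) {
      a <- x[i:(i + win - 1), j:(j + win - 1)]
      b <- y[i:(i + win - 1), j:(j + win - 1)]
      mua <- sum(wmat * a); mub <- sum(wmat * b)
      va <- sum(wmat * a * a) - mua^2
      vb <- sum(wmat * b * b) - mub^2
      vab <- sum(wmat * a * b) - mua * mub
      vals <- c(vals, ((2 * mua * mub + c1) * (2 * vab + c2)) /
                  ((mua^2 + mub^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

## central finite-difference gradient of f at x (vector-valued x)
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
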