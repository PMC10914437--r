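## Quantitative evaluation of image collections and expression edits:
## Frechet distance between feature Gaussians (dFID with a pluggable
## extractor), PSNR and SSIM for reconstruction fidelity, interpretable
## cellular features (nuclear area, membrane-marker level), and per-gene
## expression-shift significance with multiplicity adjustment.

#' Gaussian summary of a feature cloud
#'
#' @param features n x d matrix, or a mean vector (with `sigma`, `n` given).
#' @param sigma optional covariance when `features` is a mean vector.
#' @param n sample count.
#' @return object of class `feature_gaussian` with `mu`, `sigma`, `n`.
#' @export
feature_gaussian <- function(features, sigma = NULL, n = NULL) {
  if (is.null(sigma)) {
    features <- as.matrix(features)
    assert_that(nrow(features) >= 2, "need at least 2 samples")
    g <- list(mu = colMeans(features), sigma = stats::cov(features),
              n = nrow(features))
  } else {
    g <- list(mu = as.numeric(features), sigma = as.matrix(sigma),
              n = n %||% NA_integer_)
  }
  structure(g, class = "feature_gaussian")
}

## symmetric PSD square root with clipping of small negative drift
psd_sqrt <- function(m, clip_tol = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values
  vals[vals < 0 & vals > -clip_tol * max(abs(vals), 1)] <- 0
  vals <- pmax(vals, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Frechet distance between two Gaussians
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`, the squared Frechet
#' (Wasserstein-2) distance between N(mu1, S1) and N(mu2, S2).  The matrix
#' square root is computed via `sqrt(S1) S2 sqrt(S1)` with symmetrization;
#' small negative eigenvalues from numerical drift are clipped.
#'
#' @param g1,g2 [feature_gaussian()] objects of equal dimension.
#' @return nonnegative scalar.
#' @export
frechet_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "feature_gaussian"), inherits(g2, "feature_gaussian"))
  assert_that(length(g1$mu) == length(g2$mu), "dimension mismatch")
  s1h <- psd_sqrt(g1$sigma)
  cross <- psd_sqrt(s1h %*% g2$sigma %*% s1h)
  d <- sum((g1$mu - g2$mu)^2) +
    sum(diag(g1$sigma)) + sum(diag(g2$sigma)) - 2 * sum(diag(cross))
  max(d, 0)
}

#' Toy convolutional feature extractor
#'
#' A fixed-seed random strided convolutional stack (2 -> 8 -> 16 -> 64
#' channels, 3x3 kernels, stride 2, leaky-ReLU) with global average
#' pooling to a 64-dimensional embedding.  Deterministic and
#' hardware-independent; sensitive to the morphology differences present in
#' the synthetic fixtures.  A full-scale Inception-style extractor can be
#' plugged in instead wherever an `extractor` argument is accepted.
#'
#' @param seed seed for the fixed random weights.
#' @param out_dim embedding dimension.
#' @return function mapping an n x H x W x 2 array (values in `[0, 1]`)
#'   to an n x out_dim feature matrix.
#' @export
toy_extractor <- function(seed = 20240217, out_dim = 64) {
  layers <- with_seed(seed, list(
    conv2d_init(3, 2, 8),
    conv2d_init(3, 8, 16),
    conv2d_init(3, 16, out_dim)))
  function(images) {
    x <- images
    if (length(dim(x)) == 3) x <- array(x, c(1, dim(x)))
    for (l in layers) {
      x <- lrelu(conv2d_forward(l, x, stride = 2)$out)
    }
    ## global average pool
    apply(x, c(1, 4), mean)
  }
}

#' Frechet distance between two image collections (dFID)
#'
#' For each repeat, subsamples both collections, extracts features, fits
#' Gaussian summaries and computes [frechet_distance()]; reports the mean
#' and standard deviation over repeats.
#'
#' @param images_a,images_b n x H x W x C arrays (or feature matrices if
#'   `extractor = identity`).
#' @param extractor feature extractor; defaults to [toy_extractor()].
#' @param repeats number of random repeats.
#' @param subsample per-repeat subsample size (capped at collection size,
#'   sampling without replacement).
#' @param seed RNG seed for the subsampling.
#' @return list with `mean`, `sd`, `values`.
#' @export
dfid <- function(images_a, images_b, extractor = NULL, repeats = 4,
                 subsample = NULL, seed = 1L) {
  extractor <- extractor %||% toy_extractor()
  na <- dim(images_a)[1]; nb <- dim(images_b)[1]
  assert_that(na > 0 && nb > 0, "both image sets must be nonempty")
  subsample <- subsample %||% min(na, nb, 500L)
  vals <- with_seed(derive_seed(seed, 29), {
    vapply(seq_len(repeats), function(r) {
      ia <- sample(na, min(subsample, na))
      ib <- sample(nb, min(subsample, nb))
      fa <- extractor(images_a[ia, , , , drop = FALSE])
      fb <- extractor(images_b[ib, , , , drop = FALSE])
      frechet_distance(feature_gaussian(fa), feature_gaussian(fb))
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)`; identical inputs give `Inf`.
#'
#' @param x,y arrays of equal shape.
#' @param data_range dynamic range of the data.
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, data_range = 1) {
  assert_that(all(dim(x) == dim(y)) || length(x) == length(y),
              "shapes differ")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

## separable Gaussian window matrices for local moments (valid mode)
ssim_band <- function(n, win, sigma) {
  half <- (win - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  m <- matrix(0, n - win + 1, n)
  for (i in seq_len(nrow(m))) m[i, i:(i + win - 1)] <- g
  m
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), k1 = 0.01,
#' k2 = 0.03, averaged over channels; the standard single-scale form.
#'
#' @param x,y H x W or H x W x C arrays with values in `[0, data_range]`.
#' @param data_range dynamic range.
#' @param win window size (must not exceed the image).
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 stability constants.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, data_range = 1, win = 11, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03) {
  if (length(dim(x)) == 2) { x <- array(x, c(dim(x), 1)); y <- array(y, c(dim(y), 1)) }
  assert_that(all(dim(x) == dim(y)), "shapes differ")
  h <- dim(x)[1]; w <- dim(x)[2]
  assert_that(h >= win && w >= win, "image smaller than the SSIM window")
  Kr <- ssim_band(h, win, sigma)
  Kc <- ssim_band(w, win, sigma)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  smooth <- function(m) Kr %*% m %*% t(Kc)
  scores <- vapply(seq_len(dim(x)[3]), function(ch) {
    a <- x[, , ch]; b <- y[, , ch]
    mua <- smooth(a); mub <- smooth(b)
    va <- smooth(a * a) - mua^2
    vb <- smooth(b * b) - mub^2
    vab <- smooth(a * b) - mua * mub
    s <- ((2 * mua * mub + c1) * (2 * vab + c2)) /
      ((mua^2 + mub^2 + c1) * (va + vb + c2))
    mean(s)
  }, numeric(1))
  mean(scores)
}

#' Classical nuclear segmenter (Otsu + connected components)
#'
#' The built-in fallback segmenter: Otsu threshold on the nuclear channel,
#' connected-component labelling, and selection of the component covering
#' (or closest to) the crop center.  Any function with the same signature
#' (nuclear-channel matrix -> binary mask matrix) can be plugged into
#' [cellular_features()] instead, e.g. a deep segmenter.
#'
#' @param nuclear H x W matrix in `[0, 1]`.
#' @return logical H x W mask of the selected nucleus (possibly empty).
#' @export
otsu_segmenter <- function(nuclear) {
  img <- EBImage::Image(nuclear)
  th <- tryCatch(EBImage::otsu(img), error = function(e) NA_real_)
  if (is.na(th)) return(matrix(FALSE, nrow(nuclear), ncol(nuclear)))
  mask <- nuclear > th
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ctr <- (dim(nuclear) + 1) / 2
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) == 0) return(matrix(FALSE, nrow(nuclear), ncol(nuclear)))
  ## component containing (or nearest to) the center
  best <- ids[[1]]; bestd <- Inf
  for (id in ids) {
    idx <- which(lab == id, arr.ind = TRUE)
    d <- min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    if (d < bestd) { bestd <- d; best <- id }
  }
  lab == best
}

#' Interpretable cellular features of one crop
#'
#' Nuclear area = pixel count of the segmented central nucleus;
#' marker level = mean marker-channel intensity over a 3-pixel dilation
#' ring around the nucleus mask (membrane-marker convention).  An empty
#' segmentation yields area 0 with the marker averaged over the whole crop
#' and a flag set.
#'
#' @param image H x W x 2 array, channels (nuclear, marker), values in
#'   `[0, 1]`.
#' @param segmenter function(nuclear matrix) -> logical mask; defaults to
#'   [otsu_segmenter()].
#' @return list with `nuclear_area`, `marker_mean`, `flagged`.
#' @export
cellular_features <- function(image, segmenter = otsu_segmenter) {
  nuc <- image[, , 1]
  mark <- image[, , 2]
  mask <- segmenter(nuc)
  area <- sum(mask)
  if (area == 0) {
    return(list(nuclear_area = 0, marker_mean = mean(mark), flagged = TRUE))
  }
  brush <- EBImage::makeBrush(7, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  ring <- dil & !mask
  if (!any(ring)) ring <- dil
  list(nuclear_area = area, marker_mean = mean(mark[ring]), flagged = FALSE)
}

#' Cellular features for a collection of crops
#'
#' @param images n x H x W x 2 array.
#' @param segmenter see [cellular_features()].
#' @return data.frame with `cell`, `nuclear_area`, `marker_mean`, `flagged`.
#' @export
cellular_features_set <- function(images, segmenter = otsu_segmenter) {
  n <- dim(images)[1]
  out <- data.frame(cell = seq_len(n), nuclear_area = numeric(n),
                    marker_mean = numeric(n), flagged = logical(n))
  for (i in seq_len(n)) {
    f <- cellular_features(images[i, , , ], segmenter)
    out$nuclear_area[i] <- f$nuclear_area
    out$marker_mean[i] <- f$marker_mean
    out$flagged[i] <- f$flagged
  }
  out
}

p_to_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Per-gene expression-shift significance
#'
#' Two-sided Mann-Whitney U test per gene between two expression matrices,
#' with Benjamini-Hochberg adjustment across genes and conventional
#' significance stars (`****` for p <= 1e-4).
#'
#' @param values_a,values_b n x p matrices (columns = genes) or vectors
#'   (single gene).
#' @return data.frame with `gene`, `statistic`, `p`, `p_adj`, `stars`.
#' @export
expression_shift_test <- function(values_a, values_b) {
  if (is.null(dim(values_a))) values_a <- matrix(values_a, ncol = 1)
  if (is.null(dim(values_b))) values_b <- matrix(values_b, ncol = 1)
  assert_that(ncol(values_a) == ncol(values_b), "gene panels differ")
  assert_that(nrow(values_a) > 0 && nrow(values_b) > 0,
              "both samples must be nonempty")
  p <- ncol(values_a)
  stat <- pv <- numeric(p)
  for (g in seq_len(p)) {
    a <- values_a[, g]; b <- values_b[, g]
    if (length(unique(c(a, b))) == 1) {
      stat[g] <- length(a) * length(b) / 2
      pv[g] <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
      stat[g] <- unname(wt$statistic)
      pv[g] <- min(wt$p.value, 1)
    }
  }
  genes <- colnames(values_a) %||% paste0("g", seq_len(p))
  padj <- stats::p.adjust(pv, method = "BH")
  data.frame(gene = genes, statistic = stat, p = pv, p_adj = padj,
             stars = as.character(p_to_stars(padj)),
             stringsAsFactors = FALSE)
}
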