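## Synthetic CosMx-like paired data: expression tables with controlled
## second-moment structure, and two-channel (nuclear + membrane marker)
## cell images whose phenotype is causally coupled to designated driver
## genes.  Everything is a pure function of the configuration, including
## its seed.

#' Configuration for the synthetic paired ST + IF data generator
#'
#' Defines two cell populations ("normal", label 0, and "tumor", label 1)
#' whose expression vectors are rectified latent Gaussians with prescribed
#' second-moment structure, and a rendering model in which the sum of a set
#' of driver genes determines expected nuclear area (nuclear channel) and
#' mean membrane-marker intensity (marker channel).  This emulates the
#' empirical coupling between HLA-A/B2M transcript levels and CD298/B2M
#' immunofluorescence that motivates expression-guided image editing.
#'
#' @param p panel size (number of genes).
#' @param n0,n1 number of cells in population 0 (normal) and 1 (tumor).
#' @param driver_genes integer indices (1-based) of the driver genes.
#' @param sigma0,sigma1 p x p symmetric PSD latent second-moment matrices.
#' @param image_size crop edge length in pixels.
#' @param nucleus_area_map list with `slope` and `intercept`: expected
#'   nucleus area (pixels^2) = slope * driver_sum + intercept.
#' @param marker_gain scalar: expected marker intensity = gain * driver_sum,
#'   clipped to `[0, 1]`.
#' @param link expression link: `"rectified"` (real-valued, exact
#'   closed-form moments) or `"rectified-counts"` (rounded to integer
#'   counts, required for exact transcript-table round trips).
#' @param seed integer RNG seed; the entire fixture is a pure function of
#'   the configuration including this seed.
#' @param noise_sd pixel noise standard deviation.
#' @param placement_radius transcripts are scattered uniformly on the
#'   integer grid inside a disc of this radius around the cell centroid
#'   (must be < image_size / 2 so crops recover counts exactly).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(p, n0, n1, driver_genes, sigma0, sigma1,
                       image_size = 32,
                       nucleus_area_map = list(slope = 18, intercept = 25),
                       marker_gain = 0.14,
                       link = c("rectified-counts", "rectified"),
                       seed = 1L,
                       noise_sd = 0.02,
                       placement_radius = 10) {
  link <- match.arg(link)
  assert_that(p >= 2, "panel size p must be >= 2")
  assert_that(n0 >= 1 && n1 >= 1, "n0 and n1 must be >= 1")
  assert_that(all(driver_genes >= 1 & driver_genes <= p),
              "driver_genes must be indices in 1..p")
  assert_that(image_size >= 8, "image_size too small")
  assert_that(placement_radius < image_size / 2,
              "placement_radius must be smaller than image_size / 2")
  for (nm in c("sigma0", "sigma1")) {
    s <- get(nm)
    assert_that(is_square_sym(s, 1e-8) && nrow(s) == p,
                sprintf("%s must be a symmetric %d x %d matrix", nm, p, p))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      stop(sprintf("%s is not positive semidefinite (most negative eigenvalue %.3e)",
                   nm, min(ev)), call. = FALSE)
    }
  }
  structure(list(
    p = as.integer(p), n0 = as.integer(n0), n1 = as.integer(n1),
    driver_genes = as.integer(driver_genes),
    sigma0 = sigma0, sigma1 = sigma1,
    image_size = as.integer(image_size),
    nucleus_area_map = nucleus_area_map,
    marker_gain = marker_gain, link = link,
    seed = as.integer(seed), noise_sd = noise_sd,
    placement_radius = placement_radius,
    panel = paste0("g", seq_len(p))
  ), class = "sim_config")
}

#' Default study configuration
#'
#' The default conditions used throughout the package's tests and examples:
#' a 30-gene panel with two driver genes whose latent scale differs strongly
#' between populations (sd 2 in normal vs 6 in tumor, correlation 0.5/0.6),
#' so that tumor cells carry higher driver expression, larger nuclei and a
#' brighter membrane marker — a desk-scale cartoon of the normal/HCC
#' contrast in liver CosMx data.
#'
#' @param n0,n1 cells per population.
#' @param p panel size.
#' @param image_size crop edge length.
#' @param seed RNG seed.
#' @param ... passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_default_config <- function(n0 = 2000, n1 = 2000, p = 30, image_size = 32,
                               seed = 1L, ...) {
  drv <- c(1L, 2L)
  base <- diag(rep(2.5, p))
  ## mild correlation among a few non-driver pairs
  for (k in seq(3, p - 1, by = 4)) {
    base[k, k + 1] <- base[k + 1, k] <- 0.3 * 2.5
  }
  sigma0 <- base
  sigma0[drv, drv] <- matrix(c(4, 2, 2, 4), 2)
  sigma1 <- base
  sigma1[drv, drv] <- matrix(c(36, 21.6, 21.6, 36), 2)
  sim_config(p = p, n0 = n0, n1 = n1, driver_genes = drv,
             sigma0 = sigma0, sigma1 = sigma1, image_size = image_size,
             seed = seed, ...)
}

#' Closed-form second moment of a rectified mean-zero Gaussian
#'
#' For z ~ N(0, Sigma) and g = max(z, 0) elementwise,
#' E\[g_a g_b\] = s_a s_b (sqrt(1 - r^2) + r (pi/2 + asin r)) / (2 pi)
#' with r the correlation and s the marginal standard deviations; the
#' diagonal reduces to s^2 / 2.  This is the analytic target the empirical
#' scaled second moment of simulated expression converges to under the
#' `"rectified"` link.
#'
#' @param sigma latent covariance / second-moment matrix.
#' @return p x p matrix of rectified second moments.
#' @export
rectified_gaussian_moment <- function(sigma) {
  s <- sqrt(pmax(diag(sigma), 0))
  denom <- outer(s, s)
  r <- sigma / ifelse(denom > 0, denom, 1)
  r <- pmin(pmax(r, -1), 1)
  m <- denom * (sqrt(1 - r^2) + r * (pi / 2 + asin(r))) / (2 * pi)
  m[denom == 0] <- 0
  m
}

## Mean of the rectified coordinates: E[max(z,0)] = s / sqrt(2*pi).
rectified_gaussian_mean <- function(sigma) sqrt(pmax(diag(sigma), 0)) / sqrt(2 * pi)

#' Simulate an expression matrix for one population
#'
#' Draws latent vectors z ~ N(0, sigma_pop) and applies the configured link
#' (elementwise rectification, optionally rounded to integer counts).
#' Deterministic given the configuration seed and population.
#'
#' @param cfg a [sim_config()].
#' @param population 0 or 1.
#' @param n optional override of the population size.
#' @param link optional override of the configured link.
#' @return n x p nonnegative matrix with gene names as columns.
#' @export
simulate_expression <- function(cfg, population, n = NULL, link = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(population %in% c(0, 1), "population must be 0 or 1")
  sigma <- if (population == 0) cfg$sigma0 else cfg$sigma1
  n <- as.integer(n %||% (if (population == 0) cfg$n0 else cfg$n1))
  link <- link %||% cfg$link
  g <- with_seed(derive_seed(cfg$seed, 11, population), {
    z <- rmvnorm_eig(n, sigma)
    pmax(z, 0)
  })
  if (link == "rectified-counts") g <- round(g)
  colnames(g) <- cfg$panel
  g
}

## Ellipse geometry for one cell given its driver-gene sum: expected area
## from the linear area map, bounded away from zero and from the crop size,
## with multiplicative area jitter and eccentricity jitter.
nucleus_geometry <- function(driver_sum, cfg) {
  am <- cfg$nucleus_area_map
  area <- am$slope * driver_sum + am$intercept
  hw <- cfg$image_size^2
  area_exp <- min(max(area, 9), 0.2 * hw)
  jitter <- runif(1, 0.92, 1.08)
  ratio <- runif(1, 0.85, 1.18)
  area <- area_exp * jitter
  rx <- sqrt(area * ratio / pi)
  ry <- sqrt(area / (ratio * pi))
  list(rx = rx, ry = ry, area_expected = area_exp)
}

#' Render the two-channel image of one cell
#'
#' Channel 1 (nuclear, DAPI role) contains a centered ellipse whose area is
#' a linear function of the cell's driver-gene sum plus bounded jitter.
#' Channel 2 (marker, CD298/B2M role) contains an elliptical membrane ring
#' whose mean intensity is `marker_gain * driver_sum`, clipped to `[0, 1]`.
#' Pixel values are stored on the 16-bit grid so TIFF round trips are exact.
#'
#' @param expr length-p expression vector.
#' @param cfg a [sim_config()].
#' @param rng_seed integer seed for the noise realization.
#' @return H x W x 2 array in `[0, 1]`, channels (nuclear, marker).
#' @export
render_cell_image <- function(expr, cfg, rng_seed = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(length(expr) == cfg$p, "expr must have length p")
  s <- sum(expr[cfg$driver_genes])
  h <- cfg$image_size
  with_seed(derive_seed(rng_seed, 13), {
    geo <- nucleus_geometry(s, cfg)
    ctr <- floor(h / 2)
    xs <- (seq_len(h) - 1) - ctr
    ex <- outer(xs^2 / geo$rx^2, rep(1, h))
    ey <- outer(rep(1, h), xs^2 / geo$ry^2)
    d2 <- ex + ey
    nucleus <- d2 <= 1
    ring <- d2 > 1.1^2 & d2 <= 1.6^2
    marker_level <- clip01(cfg$marker_gain * s)
    ch0 <- 0.03 + 0.82 * nucleus + rnorm(h * h, 0, cfg$noise_sd)
    ch1 <- 0.02 + marker_level * ring + rnorm(h * h, 0, cfg$noise_sd)
    img <- array(0, c(h, h, 2))
    img[, , 1] <- quantize16(clip01(ch0))
    img[, , 2] <- quantize16(clip01(ch1))
    attr(img, "nucleus_area_drawn") <- sum(nucleus)
    attr(img, "marker_level") <- marker_level
    img
  })
}

#' Simulate a full paired dataset
#'
#' Simulates expression for both populations, assigns subtype labels
#' (hepatocyte-like clusters for population 0, tumor clusters for
#' population 1), and renders one two-channel image per cell.
#'
#' @param cfg a [sim_config()].
#' @return a `cellcrop_dataset`: list with `expr` (n x p), `images`
#'   (n x H x W x 2), `labels` (0/1), `subtypes`, `panel`, `cell_id`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g0 <- simulate_expression(cfg, 0)
  g1 <- simulate_expression(cfg, 1)
  expr <- rbind(g0, g1)
  n <- nrow(expr)
  labels <- c(rep(0L, cfg$n0), rep(1L, cfg$n1))
  subtypes <- with_seed(derive_seed(cfg$seed, 17), {
    c(sample(c("Hep.1", "Hep.3", "Hep.4", "Hep.5", "Hep.6"),
             cfg$n0, replace = TRUE),
      sample(c("Tumor.1", "Tumor.2"), cfg$n1, replace = TRUE,
             prob = c(0.8, 0.2)))
  })
  h <- cfg$image_size
  images <- array(0, c(n, h, h, 2))
  areas <- numeric(n)
  for (i in seq_len(n)) {
    img <- render_cell_image(expr[i, ], cfg, derive_seed(cfg$seed, 19, i))
    images[i, , , ] <- img
    areas[i] <- attr(img, "nucleus_area_drawn")
  }
  structure(list(
    expr = expr, images = images, labels = labels, subtypes = subtypes,
    panel = cfg$panel, cell_id = seq_len(n),
    nucleus_area_drawn = areas, cfg = cfg
  ), class = "cellcrop_dataset")
}

#' @export
print.cellcrop_dataset <- function(x, ...) {
  cat(sprintf("cellcrop_dataset: %d cells (%d normal / %d tumor), %d genes, %dx%dx2 images\n",
              nrow(x$expr), sum(x$labels == 0), sum(x$labels == 1),
              ncol(x$expr), dim(x$images)[2], dim(x$images)[3]))
  invisible(x)
}

#' Write a simulated dataset to disk as a CosMx-like fixture
#'
#' Lays cells out on a grid of crop-sized tiles (one FOV per slide), writes
#' the transcript table (`fov,cell_ID,target,x_global_px,y_global_px`),
#' per-cell metadata (`cell_ID,slide,subtype,cx,cy`), one 2-page 16-bit
#' TIFF per slide, and a YAML manifest with per-file checksums and the
#' intensity rescale.  Transcripts are scattered uniformly on the integer
#' grid inside a disc around each centroid, strictly inside the cell's crop
#' window, so that crop-and-sum recovers the (integer) expression exactly.
#' A small fraction of unassigned background transcripts (empty cell_ID)
#' is added to exercise downstream filtering.
#'
#' @param dataset a `cellcrop_dataset` with an integer-count link.
#' @param out_dir output directory.
#' @param overwrite overwrite an existing directory?
#' @param format transcript table format, `"csv"` or `"parquet"`
#'   (the latter requires the arrow package).
#' @param background_rate expected unassigned transcripts per cell.
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(dataset, out_dir, overwrite = FALSE,
                          format = c("csv", "parquet"),
                          background_rate = 0.5) {
  stopifnot(inherits(dataset, "cellcrop_dataset"))
  format <- match.arg(format)
  cfg <- dataset$cfg
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    if (!overwrite) stop("out_dir exists and is non-empty; use overwrite = TRUE",
                         call. = FALSE)
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!all(dataset$expr == round(dataset$expr))) {
    stop("write_fixture requires integer counts (link 'rectified-counts')",
         call. = FALSE)
  }
  h <- cfg$image_size
  half <- floor(h / 2)
  n <- nrow(dataset$expr)
  slides <- ifelse(dataset$labels == 0, "normal", "tumor")
  fovs <- ifelse(dataset$labels == 0, 1L, 2L)

  ## integer lattice points inside the placement disc
  r <- cfg$placement_radius
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]

  tx_list <- vector("list", n)
  meta <- data.frame(cell_ID = integer(n), slide = character(n),
                     subtype = character(n), cx = integer(n), cy = integer(n),
                     stringsAsFactors = FALSE)
  tiles <- list(`1` = NULL, `2` = NULL)
  tile_pos <- list()
  for (fv in c(1L, 2L)) {
    idx <- which(fovs == fv)
    ntile <- ceiling(sqrt(length(idx)))
    tiles[[as.character(fv)]] <- array(0, c(max(ntile, 1) * h, max(ntile, 1) * h, 2))
    tile_pos[[as.character(fv)]] <- list(ntile = ntile, idx = idx)
  }

  set_done <- with_seed(derive_seed(cfg$seed, 23), {
    for (fv in c(1L, 2L)) {
      tp <- tile_pos[[as.character(fv)]]
      for (k in seq_along(tp$idx)) {
        i <- tp$idx[k]
        row <- (k - 1) %/% tp$ntile
        col <- (k - 1) %% tp$ntile
        ox <- col * h
        oy <- row * h
        cx <- ox + half
        cy <- oy + half
        meta$cell_ID[i] <- i
        meta$slide[i] <- slides[i]
        meta$subtype[i] <- dataset$subtypes[i]
        meta$cx[i] <- cx
        meta$cy[i] <- cy
        counts <- dataset$expr[i, ]
        tot <- sum(counts)
        if (tot > 0) {
          gene_idx <- rep(seq_len(cfg$p), counts)
          pick <- sample(nrow(off), tot, replace = TRUE)
          tx_list[[i]] <- data.frame(
            fov = fv, cell_ID = i, target = cfg$panel[gene_idx],
            x_global_px = cx + off$dx[pick], y_global_px = cy + off$dy[pick],
            stringsAsFactors = FALSE)
        }
        tiles[[as.character(fv)]][oy + seq_len(h), ox + seq_len(h), ] <-
          dataset$images[i, , , ]
      }
    }
    ## unassigned background transcripts
    nbg <- round(background_rate * n)
    if (nbg > 0) {
      fv <- sample(c(1L, 2L), nbg, replace = TRUE)
      lims <- vapply(fv, function(f) tile_pos[[as.character(f)]]$ntile * h,
                     numeric(1))
      tx_list[[n + 1]] <- data.frame(
        fov = fv, cell_ID = NA_integer_,
        target = sample(cfg$panel, nbg, replace = TRUE),
        x_global_px = floor(runif(nbg, 0, lims)),
        y_global_px = floor(runif(nbg, 0, lims)),
        stringsAsFactors = FALSE)
    }
    TRUE
  })

  tx <- do.call(rbind, tx_list[!vapply(tx_list, is.null, logical(1))])
  if (is.null(tx)) {
    tx <- data.frame(fov = integer(0), cell_ID = integer(0),
                     target = character(0), x_global_px = integer(0),
                     y_global_px = integer(0), stringsAsFactors = FALSE)
  }
  rownames(tx) <- NULL

  tx_file <- file.path(out_dir, paste0("tx_file.", if (format == "csv") "csv" else "parquet"))
  if (format == "csv") {
    data.table::fwrite(tx, tx_file)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the arrow package", call. = FALSE)
    }
    arrow::write_parquet(tx, tx_file)
  }
  meta_file <- file.path(out_dir, "metadata.csv")
  data.table::fwrite(meta, meta_file)
  img_files <- character(0)
  for (fv in c(1L, 2L)) {
    f <- file.path(out_dir, sprintf("fov_%d.tiff", fv))
    img <- tiles[[as.character(fv)]]
    tiff::writeTIFF(list(img[, , 1], img[, , 2]), f, bits.per.sample = 16)
    img_files <- c(img_files, f)
  }
  files <- c(tx_file, meta_file, img_files)
  manifest <- list(
    format_version = "1.0",
    seed = cfg$seed,
    panel = cfg$panel,
    crop_size = h,
    n_cells = n,
    driver_genes = cfg$driver_genes,
    transcript_format = format,
    intensity_rescale = list(lo = 0, hi = 1),
    fovs = lapply(c(1L, 2L), function(fv) list(
      fov = fv, image = basename(sprintf("fov_%d.tiff", fv)),
      tiles_per_side = tile_pos[[as.character(fv)]]$ntile)),
    files = lapply(files, function(f) list(
      name = basename(f),
      md5 = unname(tools::md5sum(f))))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
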