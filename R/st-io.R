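## I/O layer for imaging-based spatial transcriptomics: transcript tables,
## per-cell sparse gene x pixel arrays, paired image crops, and subtype
## selection.  Conventions: 0-based pixel-center integer coordinates,
## half-open crop windows [c - floor(H/2), c + ceiling(H/2)).

#' Read a transcript table
#'
#' Reads the CosMx-style transcript file dialect with columns
#' `fov,cell_ID,target,x_global_px,y_global_px`.  Transcripts with a
#' missing or zero `cell_ID` (not assigned to a detected cell) are dropped;
#' the dropped count is attached as an attribute.
#'
#' @param path CSV or Parquet file.
#' @param panel character vector of gene names; unknown `target` values are
#'   an error listing the offending names.
#' @return `data.table` with columns `fov, cell_id, gene` (panel index),
#'   `x, y`; attribute `n_dropped`.
#' @export
read_transcripts <- function(path, panel) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet requires the arrow package", call. = FALSE)
    }
    tx <- data.table::as.data.table(arrow::read_parquet(path))
  } else {
    tx <- data.table::fread(path)
  }
  need <- c("fov", "cell_ID", "target", "x_global_px", "y_global_px")
  missing_cols <- setdiff(need, names(tx))
  assert_that(length(missing_cols) == 0,
              paste("transcript table lacks columns:",
                    paste(missing_cols, collapse = ", ")))
  assert_that(all(is.finite(tx$x_global_px)) && all(is.finite(tx$y_global_px)),
              "transcript coordinates must be finite")
  bad <- setdiff(unique(tx$target), panel)
  if (length(bad) > 0) {
    stop("unknown gene name(s) in transcript table: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(tx$cell_ID) & tx$cell_ID != 0
  n_dropped <- sum(!keep)
  tx <- tx[keep]
  out <- data.table::data.table(
    fov = tx$fov,
    cell_id = tx$cell_ID,
    gene = match(tx$target, panel),
    x = tx$x_global_px,
    y = tx$y_global_px)
  data.table::setattr(out, "n_dropped", n_dropped)
  out
}

crop_window <- function(center, size) {
  lo <- floor(center) - floor(size / 2)
  c(lo = lo, hi = lo + size)  # half-open [lo, hi)
}

#' Crop the sparse gene x pixel array of one cell
#'
#' Collects this cell's transcripts inside the half-open window
#' `[cx - floor(H/2), cx + ceiling(H/2)) x [cy - ..., ...)` into a sparse
#' 3-D array (gene-major).  Transcripts belonging to other cells are
#' excluded by construction.
#'
#' @param table transcript table from [read_transcripts()].
#' @param cell list or one-row data.frame with `cell_ID`, `cx`, `cy`.
#' @param crop window edge length in pixels.
#' @param panel gene names (defines the gene axis length).
#' @return object of class `cell_tx_array`: sparse triplets
#'   (`gene`, `iy`, `ix`, local 1-based) with `dim = c(p, crop, crop)`.
#' @export
crop_cell_array <- function(table, cell, crop, panel) {
  assert_that(crop > 0, "crop size must be positive")
  wx <- crop_window(cell$cx, crop)
  wy <- crop_window(cell$cy, crop)
  sub <- table[table$cell_id == cell$cell_ID &
               table$x >= wx["lo"] & table$x < wx["hi"] &
               table$y >= wy["lo"] & table$y < wy["hi"], ]
  entries <- data.table::data.table(
    gene = sub$gene,
    iy = as.integer(sub$y - wy["lo"] + 1),
    ix = as.integer(sub$x - wx["lo"] + 1))
  entries <- entries[, list(count = .N), by = c("gene", "iy", "ix")]
  structure(list(entries = entries,
                 dim = c(length(panel), crop, crop),
                 panel = panel,
                 cell_ID = cell$cell_ID,
                 window = list(x = wx, y = wy)),
            class = "cell_tx_array")
}

#' Sum a sparse cell array over its spatial dimensions
#'
#' Collapses the gene x H x W array to the 1-D per-gene count vector used
#' as the "text" modality; total mass is conserved.
#'
#' @param arr a `cell_tx_array`.
#' @return named numeric vector of length p.
#' @export
sum_expression <- function(arr) {
  stopifnot(inherits(arr, "cell_tx_array"))
  v <- numeric(arr$dim[1])
  if (nrow(arr$entries) > 0) {
    agg <- arr$entries[, list(total = sum(count)), by = "gene"]
    v[agg$gene] <- agg$total
  }
  names(v) <- arr$panel
  v
}

#' Read a multi-page FOV TIFF as an H x W x C array
#' @param path TIFF file with one page per channel.
#' @return numeric array, values in `[0, 1]` as stored.
#' @export
load_fov_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Crop the two-channel image patch of one cell
#'
#' Same centering and half-open window convention as [crop_cell_array()].
#' Regions outside the image are zero-padded and flagged.  Intensities are
#' rescaled to `[0, 1]` by the dataset-level affine transform recorded in
#' the manifest.
#'
#' @param image H x W x C array (a loaded FOV).
#' @param cell list with `cx`, `cy`.
#' @param crop window edge length.
#' @param channels length-2 integer vector (nuclear, marker page indices).
#' @param rescale list with `lo`, `hi` (affine intensity rescale).
#' @return crop x crop x 2 array with attribute `padded` (logical).
#' @export
crop_cell_image <- function(image, cell, crop, channels = c(1L, 2L),
                            rescale = list(lo = 0, hi = 1)) {
  assert_that(all(channels <= dim(image)[3]),
              "requested channel(s) beyond available image channels")
  wx <- crop_window(cell$cx, crop)
  wy <- crop_window(cell$cy, crop)
  out <- array(0, c(crop, crop, 2))
  H <- nrow(image); W <- ncol(image)
  ys <- max(wy["lo"], 0):min(wy["hi"] - 1, H - 1)
  xs <- max(wx["lo"], 0):min(wx["hi"] - 1, W - 1)
  padded <- length(ys) < crop || length(xs) < crop
  if (length(ys) > 0 && length(xs) > 0) {
    for (k in 1:2) {
      vals <- image[ys + 1, xs + 1, channels[k], drop = FALSE]
      out[ys - wy["lo"] + 1, xs - wx["lo"] + 1, k] <- vals
    }
  }
  span <- rescale$hi - rescale$lo
  if (span <= 0) span <- 1
  out <- (out - rescale$lo) / span
  attr(out, "padded") <- padded
  out
}

#' Select and relabel cell subtypes
#'
#' Retains cells whose subtype is in `normal_set` or `tumor_set`, forcing
#' the binary label to 0 for the former and 1 for the latter.
#'
#' @param dataset a `cellcrop_dataset`.
#' @param normal_set,tumor_set disjoint character vectors of subtype names.
#' @return filtered `cellcrop_dataset` with attribute `retained_fraction`.
#' @export
select_subtypes <- function(dataset, normal_set, tumor_set = character(0)) {
  stopifnot(inherits(dataset, "cellcrop_dataset"))
  both <- intersect(normal_set, tumor_set)
  assert_that(length(both) == 0,
              paste("subtypes in both normal_set and tumor_set:",
                    paste(both, collapse = ", ")))
  keep <- dataset$subtypes %in% c(normal_set, tumor_set)
  if (!any(keep)) stop("subtype selection retained no cells", call. = FALSE)
  out <- dataset
  out$expr <- dataset$expr[keep, , drop = FALSE]
  out$images <- dataset$images[keep, , , , drop = FALSE]
  out$subtypes <- dataset$subtypes[keep]
  out$cell_id <- dataset$cell_id[keep]
  if (!is.null(dataset$nucleus_area_drawn)) {
    out$nucleus_area_drawn <- dataset$nucleus_area_drawn[keep]
  }
  out$labels <- ifelse(out$subtypes %in% normal_set, 0L, 1L)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Load a written fixture back into a paired dataset
#'
#' Reads the manifest, transcript table, metadata and FOV images, then
#' rebuilds per-cell expression vectors (crop + spatial sum) and image
#' crops.  This is the reference ingestion path exercised by the
#' round-trip tests.
#'
#' @param dir fixture directory written by [write_fixture()].
#' @return a `cellcrop_dataset` (without the simulation config).
#' @export
load_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  panel <- unlist(manifest$panel)
  crop <- manifest$crop_size
  tx_name <- if (manifest$transcript_format == "csv") "tx_file.csv" else "tx_file.parquet"
  tx <- read_transcripts(file.path(dir, tx_name), panel)
  meta <- data.table::fread(file.path(dir, "metadata.csv"))
  fov_imgs <- list()
  for (fv in manifest$fovs) {
    fov_imgs[[as.character(fv$fov)]] <- load_fov_image(file.path(dir, fv$image))
  }
  n <- nrow(meta)
  expr <- matrix(0, n, length(panel), dimnames = list(NULL, panel))
  images <- array(0, c(n, crop, crop, 2))
  labels <- ifelse(meta$slide == "normal", 0L, 1L)
  rescale <- manifest$intensity_rescale
  for (i in seq_len(n)) {
    cell <- as.list(meta[i, ])
    fv <- as.character(if (labels[i] == 0) 1L else 2L)
    arr <- crop_cell_array(tx, cell, crop, panel)
    expr[i, ] <- sum_expression(arr)
    images[i, , , ] <- crop_cell_image(fov_imgs[[fv]], cell, crop,
                                       rescale = rescale)
  }
  structure(list(expr = expr, images = images, labels = labels,
                 subtypes = meta$subtype, panel = panel,
                 cell_id = meta$cell_ID, cfg = NULL),
            class = "cellcrop_dataset")
}
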