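## Covariance-matching expression editing.  A population's expression
## distribution is summarized by its scaled (uncentered) second-moment
## matrix S_i = (1/n_i) G_i' G_i = O_i diag(lam_i) O_i'.  Editing population
## i toward population j applies the fixed linear map
##     T = O_i diag(sqrt(lam_j / lam_i)) O_j'
## rowwise, which makes the edited second moment equal the target's exactly
## in the full-rank case.  A leading-eigenvalue mode rescales only the top
## eigenvalue, and a gene-restriction step confines the edit to a chosen
## gene set.

#' Scaled second-moment matrix of an expression matrix
#'
#' Returns the uncentered scaled second moment (1/n) G'G.  An optional
#' centered mode subtracts the column means first (off by default: the
#' editing algebra is defined on the uncentered moment).
#'
#' @param G n x p matrix.
#' @param center subtract column means first?
#' @return p x p symmetric PSD matrix.
#' @export
compute_scm <- function(G, center = FALSE) {
  G <- as.matrix(G)
  n <- nrow(G)
  assert_that(n >= 1, "compute_scm needs at least one row")
  if (center) G <- sweep(G, 2, colMeans(G))
  s <- crossprod(G) / n
  (s + t(s)) / 2
}

#' Eigendecomposition of a scaled second-moment matrix
#'
#' Eigenvalues are sorted nonincreasing.  Sign convention: each
#' eigenvector's largest-magnitude entry is made positive (first such entry
#' on ties), which makes the basis deterministic across calls.  Small
#' negative eigenvalues (numerical drift) are clipped to zero; negative
#' eigenvalues beyond `-1e-10 * lam[1]` are an error.
#'
#' @param scm symmetric p x p matrix.
#' @param n population size to record (metadata).
#' @return object of class `scm_decomposition` with fields `O` (orthonormal
#'   columns), `lam` (nonincreasing), `n`.
#' @export
eigendecompose <- function(scm, n = NA_integer_) {
  assert_that(is_square_sym(scm, 1e-8),
              "scm must be symmetric within tolerance")
  scm <- (scm + t(scm)) / 2
  e <- eigen(scm, symmetric = TRUE)
  lam <- e$values
  top <- max(lam[1], 0)
  if (length(lam) && min(lam) < -1e-10 * max(top, 1)) {
    stop(sprintf("matrix has a significantly negative eigenvalue (%.3e)",
                 min(lam)), call. = FALSE)
  }
  lam <- pmax(lam, 0)
  O <- e$vectors
  for (k in seq_len(ncol(O))) {
    i <- which.max(abs(O[, k]))
    if (O[i, k] < 0) O[, k] <- -O[, k]
  }
  structure(list(O = O, lam = lam, n = n), class = "scm_decomposition")
}

#' @export
print.scm_decomposition <- function(x, ...) {
  cat(sprintf("scm_decomposition: p = %d, leading eigenvalue %.4g, n = %s\n",
              length(x$lam), x$lam[1], x$n))
  invisible(x)
}

#' Editing specification
#'
#' @param mode `"full"` (match the entire spectrum) or `"leading"`
#'   (rescale only the leading eigenvalue).
#' @param edit_genes optional indices of the genes allowed to change; all
#'   other genes are frozen at their original values (see
#'   [restrict_edit()]).  `NULL` means all genes.
#' @param source,target population labels (0/1) to edit from / toward.
#' @return object of class `edit_spec`.
#' @export
edit_spec <- function(mode = c("full", "leading"), edit_genes = NULL,
                      source = 1L, target = 0L) {
  mode <- match.arg(mode)
  assert_that(source %in% c(0, 1) && target %in% c(0, 1) && source != target,
              "source and target must be distinct labels in {0, 1}")
  structure(list(mode = mode, edit_genes = edit_genes,
                 source = as.integer(source), target = as.integer(target)),
            class = "edit_spec")
}

#' Covariance-matching linear transform
#'
#' Applies `G %*% O_i diag(s) O_j'` with `s = sqrt(lam_j / lam_i)` in full
#' mode (so the edited scaled second moment equals the target's exactly for
#' full-rank populations) or `s = (sqrt(lam_j[1] / lam_i[1]), 1, ..., 1)` in
#' leading mode.  Directions with a (numerically) zero source eigenvalue get
#' scale 0, the pseudo-inverse rule.  When source and target decompositions
#' are identical the input is returned unchanged, bit-exactly.
#'
#' @param G n x p matrix of the source population.
#' @param dec_i source [eigendecompose()] result.
#' @param dec_j target decomposition (same panel).
#' @param mode `"full"` or `"leading"`.
#' @return edited n x p matrix (real-valued; may contain negatives).
#' @export
match_transform <- function(G, dec_i, dec_j, mode = c("full", "leading")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dec_i, "scm_decomposition"),
            inherits(dec_j, "scm_decomposition"))
  p <- length(dec_i$lam)
  assert_that(length(dec_j$lam) == p, "decompositions are from different panels")
  assert_that(ncol(G) == p, "G has the wrong number of columns")
  if (dec_i$lam[1] <= 0) {
    stop("source population is all-zero (leading eigenvalue 0); cannot edit",
         call. = FALSE)
  }
  if (identical(dec_i$O, dec_j$O) && identical(dec_i$lam, dec_j$lam)) {
    return(G)  # self-edit is the identity map
  }
  tol <- 1e-12 * dec_i$lam[1]
  if (mode == "full") {
    s <- ifelse(dec_i$lam > tol, sqrt(dec_j$lam / pmax(dec_i$lam, tol)), 0)
  } else {
    s <- rep(1, p)
    s[1] <- sqrt(dec_j$lam[1] / dec_i$lam[1])
  }
  Tm <- dec_i$O %*% (s * t(dec_j$O))
  out <- as.matrix(G) %*% Tm
  colnames(out) <- colnames(G)
  out
}

#' Restrict an edit to a gene subset
#'
#' Returns a matrix whose columns equal the edited matrix on `edit_genes`
#' and the original matrix elsewhere: the complement of `edit_genes` is
#' kept unchanged, narrowing the edit to the genes of interest.
#'
#' @param G original n x p matrix.
#' @param G_edit fully edited matrix of the same shape.
#' @param edit_genes indices of the genes allowed to change (`NULL` = all).
#' @return masked matrix.
#' @export
restrict_edit <- function(G, G_edit, edit_genes = NULL) {
  assert_that(all(dim(G) == dim(G_edit)), "matrices must have equal shape")
  if (is.null(edit_genes)) return(G_edit)
  edit_genes <- as.integer(edit_genes)
  assert_that(all(edit_genes >= 1 & edit_genes <= ncol(G)),
              "edit_genes out of range")
  out <- G
  out[, edit_genes] <- G_edit[, edit_genes]
  out
}

#' Edit one population's expression toward another's
#'
#' Orchestrates [compute_scm()], [eigendecompose()], [match_transform()] and
#' [restrict_edit()] on a paired dataset, and records provenance: mode,
#' edited genes, leading-eigenvalue ratio, and the achieved relative
#' Frobenius residual between the edited and target second moments (for the
#' unrestricted transform this is numerically zero in full mode).
#'
#' @param dataset a `cellcrop_dataset` containing both populations.
#' @param spec an [edit_spec()].
#' @return list with `expr_edited` (rows of the source population, edited),
#'   `index` (row indices of the source population in the dataset),
#'   `provenance`.
#' @export
edit_population <- function(dataset, spec) {
  stopifnot(inherits(dataset, "cellcrop_dataset"), inherits(spec, "edit_spec"))
  idx_src <- which(dataset$labels == spec$source)
  idx_tgt <- which(dataset$labels == spec$target)
  assert_that(length(idx_src) > 0 && length(idx_tgt) > 0,
              "dataset must contain both populations")
  G_src <- dataset$expr[idx_src, , drop = FALSE]
  G_tgt <- dataset$expr[idx_tgt, , drop = FALSE]
  S_src <- compute_scm(G_src)
  S_tgt <- compute_scm(G_tgt)
  dec_src <- eigendecompose(S_src, n = nrow(G_src))
  dec_tgt <- eigendecompose(S_tgt, n = nrow(G_tgt))
  G_full <- match_transform(G_src, dec_src, dec_tgt, mode = spec$mode)
  G_out <- restrict_edit(G_src, G_full, spec$edit_genes)
  residual_full <- rel_frobenius(compute_scm(G_full), S_tgt)
  residual_out <- rel_frobenius(compute_scm(G_out), S_tgt)
  list(
    expr_edited = G_out,
    index = idx_src,
    provenance = list(
      mode = spec$mode,
      source = spec$source, target = spec$target,
      edit_genes = spec$edit_genes,
      leading_eigenvalue_ratio = dec_tgt$lam[1] / dec_src$lam[1],
      scm_residual_unrestricted = residual_full,
      scm_residual = residual_out))
}

#' Write an edited matrix with its provenance sidecar
#'
#' @param edited result of [edit_population()].
#' @param path output CSV (or Parquet if the arrow package is available and
#'   the path ends in `.parquet`).
#' @export
write_edited <- function(edited, path) {
  df <- data.table::as.data.table(edited$expr_edited)
  if (grepl("\\.parquet$", path) && requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(df, path)
  } else {
    data.table::fwrite(df, path)
  }
  yaml::write_yaml(edited$provenance, paste0(path, ".provenance.yaml"))
  invisible(path)
}
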