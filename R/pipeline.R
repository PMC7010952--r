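#' Combined 440-dimensional raw feature of a protein
#'
#' Concatenates the 40-dimensional F-vector and the 400-dimensional
#' composition/transition descriptor, F first.
#'
#' @param seq Protein sequence.
#' @param L Segments for the CT descriptor (default 4).
#' @return Numeric vector of length 440 (when `L = 4`).
#' @export
raw_feature <- function(seq, L = 4L) {
  c(f_vector(seq), ct_vector(seq, L = L))
}

#' Encode a set of proteins into a raw feature matrix
#'
#' @param proteins Data frame with columns `id`, `sequence` (as returned by
#'   [read_fasta()] or [generate_synthetic()]).
#' @param L Segments for the CT descriptor.
#' @return Numeric matrix, one row per protein (rownames = ids), 440 columns.
#' @export
encode_proteins <- function(proteins, L = 4L) {
  stopifnot(is.data.frame(proteins), all(c("id","sequence") %in% names(proteins)))
  rows <- lapply(proteins$sequence, raw_feature, L = L)
  m <- do.call(rbind, rows)
  rownames(m) <- proteins$id
  m
}

#' Fit a PCA reconstruction model
#'
#' Mean-centred principal component analysis of the raw feature matrix,
#' keeping the first `k` axes (default 30). Component signs are fixed so the
#' largest-magnitude loading of each axis is positive, making the projection
#' deterministic. Optional per-feature unit-variance scaling is available
#' because the percent-scale CT block otherwise dominates the circle-scale
#' F block.
#'
#' @param features Samples x features numeric matrix.
#' @param k Number of components to keep.
#' @param scale. Scale features to unit variance before rotation
#'   (default `FALSE`: plain mean-centred PCA).
#' @return Object of class `pca_model` with elements `mean`, `scale`,
#'   `components` (k x p, orthonormal rows), `explained_ratio`, `k`.
#' @export
fit_pca <- function(features, k = 30L, scale. = FALSE) {
  stopifnot(is.matrix(features))
  n <- nrow(features); p <- ncol(features)
  if (n < 2L) stop("need at least 2 samples to fit PCA")
  if (k < 1L || k > min(p, n - 1L)) {
    stop(sprintf("k must be in 1..min(%d, %d); got %d", p, n - 1L, k))
  }
  scl <- rep(1, p)
  if (scale.) {
    sds <- apply(features, 2, stats::sd)
    scl <- ifelse(sds > 0, sds, 1)  # constant features pass through unscaled
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = if (scale.) scl else FALSE)
  rot <- t(pc$rotation[, seq_len(k), drop = FALSE])  # k x p
  # sign convention: largest-|loading| entry of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(rot[i, ]))
    if (rot[i, j] < 0) rot[i, ] <- -rot[i, ]
  }
  var_all <- pc$sdev^2
  structure(list(
    mean = pc$center,
    scale = scl,
    components = rot,
    explained_ratio = var_all[seq_len(k)] / sum(var_all),
    k = as.integer(k)
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components over %d features; cumulative explained %.1f%%\n",
              x$k, length(x$mean), 100 * sum(x$explained_ratio)))
  invisible(x)
}

#' Project a raw feature vector with a fitted PCA model
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param feat Numeric vector (length = number of features the model was
#'   fitted on) or a samples x features matrix.
#' @return Numeric vector of length `k`, or a samples x k matrix.
#' @export
project <- function(model, feat) {
  stopifnot(inherits(model, "pca_model"))
  p <- length(model$mean)
  if (is.matrix(feat)) {
    if (ncol(feat) != p) stop("feature dimension mismatch")
    centred <- sweep(sweep(feat, 2, model$mean), 2, model$scale, "/")
    out <- centred %*% t(model$components)
    rownames(out) <- rownames(feat)
    return(out)
  }
  if (length(feat) != p) stop("feature dimension mismatch")
  as.numeric(model$components %*% ((feat - model$mean) / model$scale))
}

#' Concatenate two projected protein features into a pair vector
#'
#' @param va,vb Equal-length numeric vectors (projected features of the two
#'   partners, in pair order).
#' @return Numeric vector of length `2 * length(va)` (60 with k = 30).
#' @export
pair_vector <- function(va, vb) {
  if (length(va) != length(vb)) stop("pair members must have equal dimensions")
  c(va, vb)
}

#' Serialize / restore a PCA model as JSON text
#'
#' Flat text artifact holding mean, scale, component rows and explained
#' variance ratios.
#'
#' @param model A `pca_model`.
#' @param path File path.
#' @return `read_pca_model` returns a `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  obj <- list(mean = unname(model$mean), scale = unname(model$scale),
              components = model$components,
              explained_ratio = model$explained_ratio, k = model$k)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean = as.numeric(obj$mean), scale = as.numeric(obj$scale),
    components = matrix(as.numeric(obj$components), nrow = obj$k),
    explained_ratio = as.numeric(obj$explained_ratio),
    k = as.integer(obj$k)
  ), class = "pca_model")
}
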