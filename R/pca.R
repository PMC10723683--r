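#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance matrix (divisor n-1) of the
#' vectorized aligned coordinates. Only components with nonnegligible
#' variance are retained, so m <= min(n-1, 3K). Eigenvector signs follow
#' the convention that each column's largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param shapes n x 3K matrix of aligned shapes (rows = specimens), e.g.
#'   `as_shape_matrix(gpa$aligned)`.
#' @return A `pca_model`: list with `mean_vector`, `eigenvectors`
#'   (3K x m, orthonormal columns), `eigenvalues` (descending), `scores`
#'   (n x m, centered).
#' @export
fit_pca <- function(shapes) {
  shapes <- as.matrix(shapes)
  n <- nrow(shapes)
  if (n < 3L) stop("PCA needs n >= 3 specimens")
  mean_vector <- colMeans(shapes)
  x <- sweep(shapes, 2, mean_vector)
  # eigen via SVD of the centered data: stable for 3K >> n
  sv <- svd(x, nu = 0)
  eigenvalues <- sv$d^2 / (n - 1)
  keep <- eigenvalues > max(eigenvalues[1], .Machine$double.eps) * 1e-12
  eigenvalues <- eigenvalues[keep]
  vectors <- sv$v[, keep, drop = FALSE]
  flip <- vapply(seq_len(ncol(vectors)), function(j) {
    v <- vectors[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  vectors <- sweep(vectors, 2, flip, `*`)
  scores <- x %*% vectors
  rownames(scores) <- rownames(shapes)
  colnames(scores) <- colnames(vectors) <- paste0("PC", seq_along(eigenvalues))
  structure(list(mean_vector = mean_vector, eigenvectors = vectors,
                 eigenvalues = eigenvalues, scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<pca_model> %d specimens, %d components; PC1-3: %s%% variance\n",
              nrow(x$scores), length(x$eigenvalues),
              paste(sprintf("%.1f", utils::head(pct, 3)), collapse = "/")))
  invisible(x)
}

#' Project shape vectors into an existing PCA space
#'
#' @param model A `pca_model` from [fit_pca].
#' @param shapes Length-3K vector or n x 3K matrix of shape coordinates.
#' @return Score vector/matrix `(x - mean) %*% eigenvectors`.
#' @export
project_pca <- function(model, shapes) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(shapes))) shapes <- matrix(shapes, nrow = 1)
  if (ncol(shapes) != length(model$mean_vector))
    stop("shape vector length ", ncol(shapes), " != 3K = ",
         length(model$mean_vector))
  sweep(as.matrix(shapes), 2, model$mean_vector) %*% model$eigenvectors
}
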