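#' Reconstruct the extreme shape along a canonical axis
#'
#' Composes the two linear maps of the pipeline to visualize what a
#' canonical axis means in landmark space: the canonical vector (defined
#' on the PC subset) is back-projected through the PC eigenvectors into
#' shape space, scaled by a canonical score, and added to the mean shape.
#' A score of 0 returns the GPA consensus; the minimum and maximum
#' observed score on the axis give the two extremes drawn on ordination
#' plots.
#'
#' @param pca A `pca_model`.
#' @param model A `cva_model` fitted on the leading PCs of `pca`.
#' @param axis Canonical axis index (1-based).
#' @param score Canonical score at which to evaluate the shape.
#' @return K x 3 landmark matrix.
#' @export
extreme_shape <- function(pca, model, axis, score) {
  stopifnot(inherits(pca, "pca_model"), inherits(model, "cva_model"))
  c_axes <- ncol(model$canonical_vectors)
  if (axis < 1L || axis > c_axes)
    stop("axis must be in 1..", c_axes)
  a <- model$canonical_vectors[, axis]
  shape_dir <- pca$eigenvectors[, seq_len(model$n_pcs), drop = FALSE] %*% a
  unflatten_coords(pca$mean_vector + score * as.vector(shape_dir))
}
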