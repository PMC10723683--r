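#' Centroid size of a configuration
#'
#' The square root of the summed squared Euclidean distances of all
#' landmarks from their centroid — the size variable removed by Procrustes
#' scaling and used by the allometry tests.
#'
#' @param config A [landmark_config] or a plain K x 3 matrix.
#' @return Positive scalar (0 for a single point).
#' @export
centroid_size <- function(config) {
  m <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  if (!all(is.finite(m))) stop("non-finite coordinates")
  cen <- colMeans(m)
  sqrt(sum(sweep(m, 2, cen)^2))
}

center_coords <- function(m) sweep(m, 2, colMeans(m))

#' Optimal least-squares rotation between two centered configurations
#'
#' Returns the proper rotation R (det +1, orthonormal) minimizing
#' ||A R - B||_F, via the singular value decomposition of crossprod(A, B)
#' with the smallest singular value sign-corrected so reflections are
#' never introduced.
#'
#' @param A,B Centered K x 3 matrices.
#' @return A 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)))
  M <- crossprod(A, B)            # t(A) %*% B
  if (all(abs(M) < .Machine$double.eps))
    stop("degenerate (rank-0) configuration: rotation undefined")
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Generalized Procrustes superimposition
#'
#' Iteratively superimposes all configurations of a dataset: each is
#' centered, (optionally) scaled to unit centroid size, and rotated to the
#' running consensus; the consensus is the arithmetic mean of the aligned
#' configurations, renormalized to unit centroid size. The first specimen
#' (centered/scaled) initializes the consensus, making the result
#' deterministic in the input order. Iteration stops when the
#' root-mean-square change of the consensus falls below `tol`.
#'
#' Left antimeres must already be mirrored (see [mirror_lefts]); reflection
#' is never part of the fitted transformation. Semilandmarks are treated as
#' fixed points (no sliding).
#'
#' @param dataset An [edj_dataset] (or list of K x 3 matrices) with at
#'   least 2 configurations of equal K.
#' @param scale Remove size by scaling each configuration to unit centroid
#'   size (full Procrustes, the default). With `scale = FALSE` sizes are
#'   retained (partial Procrustes).
#' @param tol Convergence tolerance on the RMS consensus change.
#' @param max_iter Iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`.
#' @return A `procrustes_result`: list with `aligned` (named list of K x 3
#'   matrices), `consensus` (K x 3, unit centroid size), `centroid_sizes`
#'   (original units), `n_iterations`, `converged`.
#' @export
generalized_procrustes <- function(dataset, scale = TRUE, tol = 1e-10,
                                   max_iter = 100L) {
  mats <- if (inherits(dataset, "edj_dataset"))
    lapply(dataset$configurations, function(cf) cf$coords)
  else lapply(dataset, as.matrix)
  n <- length(mats)
  if (n < 2L) stop("GPA needs at least 2 configurations")
  ks <- vapply(mats, nrow, integer(1))
  if (length(unique(ks)) > 1L) stop("configurations differ in K")
  sizes <- vapply(mats, centroid_size, numeric(1))
  if (any(sizes <= 0)) stop("degenerate configuration with zero size")
  aligned <- lapply(seq_len(n), function(i) {
    m <- center_coords(mats[[i]])
    if (scale) m / sizes[i] else m
  })
  consensus <- aligned[[1]] / centroid_size(aligned[[1]])
  n_iter <- 0L; converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    aligned <- lapply(aligned, function(m) m %*% optimal_rotation(m, consensus))
    new_consensus <- Reduce(`+`, aligned) / n
    new_consensus <- new_consensus / centroid_size(new_consensus)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  names(aligned) <- names(mats)
  names(sizes) <- names(mats)
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, n_iterations = n_iter,
                 converged = converged, scale = scale),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> %d specimens, K=%d, %d iterations (%s)\n",
              length(x$aligned), nrow(x$consensus), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Ordinary Procrustes fit of one configuration onto a consensus
#'
#' Centers, unit-scales and rotates a single configuration onto a fixed
#' consensus shape — the operation that places held-out or new specimens
#' into an existing GPA space.
#'
#' @param config A [landmark_config] or K x 3 matrix.
#' @param consensus K x 3 reference shape.
#' @param scale Scale to unit centroid size (default `TRUE`).
#' @return The aligned K x 3 matrix.
#' @export
ordinary_procrustes_fit <- function(config, consensus, scale = TRUE) {
  m <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  consensus <- as.matrix(consensus)
  if (!identical(dim(m), dim(consensus)))
    stop("configuration and consensus differ in dimensions")
  m <- center_coords(m)
  if (scale) m <- m / centroid_size(m)
  cc <- center_coords(consensus)
  m %*% optimal_rotation(m, cc)
}

#' Procrustes distance between two aligned shapes
#'
#' Root summed squared difference after optimally rotating `a` onto `b`
#' (both centered and unit-scaled first).
#'
#' @param a,b K x 3 matrices or [landmark_config] objects.
#' @return Nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  bm <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  bm <- center_coords(bm); bm <- bm / centroid_size(bm)
  am <- ordinary_procrustes_fit(a, bm)
  sqrt(sum((am - bm)^2))
}
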