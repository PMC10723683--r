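#' Canonical variate analysis on a subset of PC scores
#'
#' Fits the between/within generalized eigenproblem on the first `n_pcs`
#' principal component scores with group labels (geographic origin or
#' species). The pooled within-group covariance W uses divisor n - G; the
#' between-group covariance B is built from group means weighted by group
#' size with divisor G - 1. Canonical vectors a are eigenvectors of
#' W^{-1} B scaled so that a' W a = 1, which makes Euclidean distance in
#' canonical-score space the Mahalanobis distance under W; the pooled
#' within-group covariance of the canonical scores is therefore the
#' identity. Axis signs follow the largest-magnitude-loading-positive
#' convention.
#'
#' @param scores n x n_pcs matrix of PC scores (rows = specimens used for
#'   fitting; a posteriori specimens are excluded by the caller).
#' @param groups Character/factor vector of length n; group order is the
#'   order of first appearance unless `groups` is a factor.
#' @return A `cva_model`: list with `n_pcs`, `groups` (ordered labels),
#'   `group_means` (G x n_pcs), `pooled_within`, `canonical_vectors`
#'   (n_pcs x c), `eigenvalues`, `pct_variance`, `cv_scores` (n x c),
#'   `cv_group_means` (G x c), `grand_mean`, `group_sizes`.
#' @export
fit_cva <- function(scores, groups) {
  scores <- as.matrix(scores)
  n <- nrow(scores); p <- ncol(scores)
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups, levels = unique(as.character(groups)))
  if (length(groups) != n) stop("length(groups) != nrow(scores)")
  levs <- levels(groups)
  G <- length(levs)
  if (G < 2L) stop("CVA needs at least 2 groups")
  sizes <- as.integer(table(groups)[levs])
  if (any(sizes < 2L))
    stop("every group needs >= 2 members (", levs[sizes < 2][1], " has ",
         min(sizes), ")")
  if (n - G < p)
    stop("pooled within-group covariance singular: need n - G >= n_pcs; ",
         "reduce n_pcs (have n=", n, ", G=", G, ", n_pcs=", p, ")")
  grand_mean <- colMeans(scores)
  gm <- do.call(rbind, lapply(levs, function(g)
    colMeans(scores[groups == g, , drop = FALSE])))
  rownames(gm) <- levs
  W <- matrix(0, p, p)
  for (g in levs) {
    xg <- sweep(scores[groups == g, , drop = FALSE], 2, gm[g, ])
    W <- W + crossprod(xg)
  }
  W <- W / (n - G)
  dm <- sweep(gm, 2, grand_mean)
  B <- crossprod(dm * sqrt(sizes)) / (G - 1)
  # generalized eigenproblem B a = lambda W a via Cholesky whitening
  L <- tryCatch(chol(W), error = function(e)
    stop("singular pooled within-group covariance; reduce n_pcs"))
  Linv <- backsolve(L, diag(p))       # W = L'L, Linv = L^{-1}
  M <- t(Linv) %*% B %*% Linv
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  c_axes <- min(G - 1L, p)
  lambda <- pmax(ee$values[seq_len(c_axes)], 0)
  A <- Linv %*% ee$vectors[, seq_len(c_axes), drop = FALSE]  # a'Wa = 1
  flip <- vapply(seq_len(ncol(A)), function(j)
    sign(A[which.max(abs(A[, j])), j]), numeric(1))
  A <- sweep(A, 2, flip, `*`)
  cv_scores <- sweep(scores, 2, grand_mean) %*% A
  colnames(cv_scores) <- colnames(A) <- paste0("CV", seq_len(c_axes))
  rownames(cv_scores) <- rownames(scores)
  cv_gm <- sweep(gm, 2, grand_mean) %*% A
  structure(list(n_pcs = p, groups = levs, group_means = gm,
                 pooled_within = W, canonical_vectors = A,
                 eigenvalues = lambda,
                 pct_variance = 100 * lambda / sum(lambda),
                 cv_scores = cv_scores, cv_group_means = cv_gm,
                 grand_mean = grand_mean, group_sizes = sizes),
            class = "cva_model")
}

#' @export
print.cva_model <- function(x, ...) {
  cat(sprintf("<cva_model> %d groups on %d PCs; CV variance: %s%%\n",
              length(x$groups), x$n_pcs,
              paste(sprintf("%.2f", x$pct_variance), collapse = "/")))
  invisible(x)
}

#' Classify score vectors to the nearest group in canonical space
#'
#' Assigns each PC-score vector to the group whose centroid is nearest in
#' canonical-score space (Euclidean there = Mahalanobis under the pooled
#' within-group covariance restricted to the canonical subspace). Ties go
#' to the earlier group in `model$groups`.
#'
#' @param model A `cva_model`.
#' @param scores Length-n_pcs vector or matrix of PC scores.
#' @return Character vector of predicted group labels.
#' @export
classify_cva <- function(model, scores) {
  stopifnot(inherits(model, "cva_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != model$n_pcs)
    stop("score vector length ", ncol(scores), " != n_pcs = ", model$n_pcs)
  cv <- sweep(as.matrix(scores), 2, model$grand_mean) %*%
    model$canonical_vectors
  d2 <- outer(rowSums(cv^2), rowSums(model$cv_group_means^2), `+`) -
    2 * cv %*% t(model$cv_group_means)
  model$groups[apply(d2, 1, which.min)]  # which.min takes first on ties
}

#' Jackknife (leave-one-out) cross-validated classification
#'
#' For each specimen the CVA is refitted — group means, pooled
#' within-group covariance and canonical vectors — on the remaining n - 1
#' specimens using the same fixed PC scores (the PCA is not recomputed),
#' and the held-out specimen is classified. Folds whose removal would
#' empty a group (or make W singular) are skipped with a warning and
#' recorded.
#'
#' @param scores n x p matrix of PC scores (p >= n_pcs).
#' @param groups Group labels, length n.
#' @param n_pcs Number of leading PC columns used.
#' @return A `classification_table`: list with `groups`, `counts` (G x G,
#'   true x predicted), `percentages` (rows sum to 100),
#'   `per_group_accuracy`, `overall_accuracy` (both in percent),
#'   `predicted` (per-specimen labels, NA where skipped), `skipped`.
#' @export
jackknife_classification <- function(scores, groups, n_pcs = ncol(scores)) {
  scores <- as.matrix(scores)[, seq_len(n_pcs), drop = FALSE]
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups, levels = unique(as.character(groups)))
  n <- nrow(scores)
  levs <- levels(groups)
  predicted <- rep(NA_character_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    gi <- groups[-i]
    if (min(table(gi)[unique(as.character(gi))]) < 2L) {
      skipped <- c(skipped, i); next
    }
    fit <- tryCatch(fit_cva(scores[-i, , drop = FALSE], gi),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, i); next }
    predicted[i] <- classify_cva(fit, scores[i, ])
  }
  if (length(skipped))
    warning(length(skipped), " jackknife fold(s) skipped (group emptied ",
            "or singular covariance)")
  used <- !is.na(predicted)
  counts <- table(factor(as.character(groups)[used], levels = levs),
                  factor(predicted[used], levels = levs))
  counts <- unclass(as.matrix(counts))
  pct <- 100 * counts / pmax(rowSums(counts), 1)
  per_group <- 100 * diag(counts) / pmax(rowSums(counts), 1)
  structure(list(groups = levs, counts = counts, percentages = pct,
                 per_group_accuracy = per_group,
                 overall_accuracy = 100 * sum(diag(counts)) / sum(counts),
                 predicted = predicted, skipped = skipped),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("<classification_table> overall accuracy %.1f%%\n",
              x$overall_accuracy))
  print(x$counts)
  invisible(x)
}

#' Select the number of PCs by screening jackknife accuracy
#'
#' Runs [jackknife_classification] on the first k PCs for every k in
#' `[k_min, k_max]` and returns the smallest k whose overall accuracy
#' attains the maximum over the screen — the minimum number of PC scores
#' reaching the optimum of correct classification.
#'
#' @param scores n x p matrix of PC scores.
#' @param groups Group labels.
#' @param k_min,k_max Screening range; `k_max` is capped at the largest
#'   feasible k (`n - G`) and at `ncol(scores)`.
#' @return Integer, with attribute `"accuracy"` giving the full screen.
#' @export
select_pc_count <- function(scores, groups, k_min = 2L, k_max = NULL) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  G <- length(unique(groups))
  cap <- min(ncol(scores), nrow(scores) - G)
  if (is.null(k_max)) k_max <- cap
  k_max <- min(k_max, cap)
  if (k_min > k_max) stop("empty screening range: k_min > ", k_max)
  ks <- k_min:k_max
  acc <- vapply(ks, function(k)
    suppressWarnings(
      jackknife_classification(scores, groups, n_pcs = k)$overall_accuracy),
    numeric(1))
  names(acc) <- ks
  best <- ks[which(acc == max(acc))[1]]
  structure(as.integer(best), accuracy = acc)
}

#' Project held-out specimens a posteriori into a fitted CVA
#'
#' Specimens excluded from CVA fitting (small sites, paleoproteomic
#' specimens) but present in the GPA/PCA are placed in the canonical
#' plots: their PC scores are truncated to the model's n_pcs, centered by
#' the training grand mean and projected on the canonical vectors.
#'
#' @param model A `cva_model`.
#' @param pca A `pca_model` from the same analysis.
#' @param shapes Length-3K vector or n x 3K matrix of aligned shape
#'   coordinates.
#' @return Matrix of canonical scores (rows = specimens).
#' @export
project_posteriori <- function(model, pca, shapes) {
  stopifnot(inherits(model, "cva_model"), inherits(pca, "pca_model"))
  pc <- project_pca(pca, shapes)
  if (ncol(pc) < model$n_pcs)
    stop("PCA provides ", ncol(pc), " PCs; model needs ", model$n_pcs)
  pc <- pc[, seq_len(model$n_pcs), drop = FALSE]
  out <- sweep(pc, 2, model$grand_mean) %*% model$canonical_vectors
  colnames(out) <- colnames(model$canonical_vectors)
  out
}

#' Typicality probabilities of specimens with respect to each group
#'
#' For each specimen and group, the squared distance D2 to the group
#' centroid in canonical-score space (Euclidean there = Mahalanobis under
#' the pooled within-group covariance) is referred to the upper tail of
#' the chi-square distribution: P(chi2_df >= D2). Low values flag
#' specimens atypical of that group; a specimen exactly at a centroid has
#' typicality 1. The default df is the number of canonical axes (the
#' space the distance is measured in); `df_mode = "n_pcs"` uses the
#' pre-CVA dimensionality instead.
#'
#' @param model A `cva_model`.
#' @param cv_scores Matrix of canonical scores (e.g. `model$cv_scores` or
#'   [project_posteriori] output).
#' @param df_mode `"n_cv"` (default) or `"n_pcs"`.
#' @return A `data.frame` with `specimen_id` and one probability column
#'   per group; squared distances in attribute `"d2"`.
#' @export
typicality_probabilities <- function(model, cv_scores,
                                     df_mode = c("n_cv", "n_pcs")) {
  stopifnot(inherits(model, "cva_model"))
  df_mode <- match.arg(df_mode)
  cv <- as.matrix(cv_scores)
  if (ncol(cv) != ncol(model$cv_group_means))
    stop("canonical score dimension mismatch")
  df <- if (df_mode == "n_cv") ncol(cv) else model$n_pcs
  d2 <- outer(rowSums(cv^2), rowSums(model$cv_group_means^2), `+`) -
    2 * cv %*% t(model$cv_group_means)
  d2 <- pmax(d2, 0)
  probs <- stats::pchisq(d2, df = df, lower.tail = FALSE)
  colnames(probs) <- colnames(d2) <- model$groups
  out <- data.frame(specimen_id = rownames(cv) %||%
                      paste0("specimen_", seq_len(nrow(cv))),
                    probs, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "d2") <- d2
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
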