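#' Allometry test: centroid size against canonical variates
#'
#' Pearson correlation between centroid size and each canonical axis, with
#' the two-sided p-value from the t distribution on n - 2 degrees of
#' freedom, plus the squared correlation coefficient. Raw centroid size is
#' used by default; `log_size = TRUE` substitutes log centroid size.
#'
#' @param centroid_sizes Numeric vector, one size per specimen.
#' @param cv_scores n x c matrix of canonical scores.
#' @param log_size Correlate against log centroid size instead.
#' @return A `data.frame` with one row per axis: `axis`, `r`, `p_value`,
#'   `r_squared`.
#' @export
allometry_test <- function(centroid_sizes, cv_scores, log_size = FALSE) {
  cv <- as.matrix(cv_scores)
  s <- as.numeric(centroid_sizes)
  if (length(s) != nrow(cv))
    stop("length(centroid_sizes) != nrow(cv_scores)")
  if (length(s) < 3L) stop("allometry test needs n >= 3")
  if (stats::sd(s) == 0) stop("zero variance in centroid sizes")
  if (log_size) s <- log(s)
  res <- lapply(seq_len(ncol(cv)), function(j) {
    ct <- stats::cor.test(s, cv[, j], method = "pearson",
                          alternative = "two.sided")
    data.frame(axis = colnames(cv)[j] %||% paste0("CV", j),
               r = unname(ct$estimate), p_value = ct$p.value,
               r_squared = unname(ct$estimate)^2)
  })
  do.call(rbind, res)
}
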