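#' Run the full EDJ shape-analysis pipeline
#'
#' Orchestrates every stage on one dataset: mirroring of left antimeres,
#' generalized Procrustes superimposition, PCA of the shape coordinates,
#' PC-subset selection by jackknife screening (or a fixed `n_pcs`), CVA on
#' the fitting specimens (a posteriori-flagged specimens are excluded from
#' fitting but projected afterwards), jackknife classification, typicality
#' probabilities for the projected specimens, allometry tests against
#' centroid size, and the extreme shapes at the observed score range of
#' each canonical axis.
#'
#' @param dataset An [edj_dataset] whose records carry `group` and
#'   `posteriori_flag`.
#' @param subset Optional molar-position filter: `"M1-M2"`, `"M3"` or
#'   `"all"` (default) using the records' `molar_position`.
#' @param n_pcs Fixed PC-subset size; `NULL` (default) screens with
#'   [select_pc_count].
#' @param k_max Upper bound of the screening range.
#' @param df_mode Degrees-of-freedom convention for
#'   [typicality_probabilities].
#' @param out_dir Optional directory; when given, all tables are written
#'   as CSV (aligned coordinates, centroid sizes, PC scores, CV scores,
#'   classification frequencies and percentages, typicalities, allometry,
#'   extreme shapes) plus a JSON run log.
#' @return An `edj_pipeline` list with elements `gpa`, `pca`, `n_pcs`,
#'   `cva`, `classification`, `posteriori_scores`, `typicality`,
#'   `allometry`, `extremes`, `records`.
#' @export
run_pipeline <- function(dataset, subset = c("all", "M1-M2", "M3"),
                         n_pcs = NULL, k_max = NULL,
                         df_mode = "n_cv", out_dir = NULL) {
  stopifnot(inherits(dataset, "edj_dataset"))
  subset <- match.arg(subset)
  t0 <- Sys.time()
  rec <- dataset$records
  if (subset != "all") {
    keep_pos <- if (subset == "M1-M2") c("M1", "M2") else "M3"
    dataset <- subset_dataset(dataset,
                              rec$specimen_id[rec$molar_position %in% keep_pos])
    rec <- dataset$records
  }
  dataset <- mirror_lefts(dataset)
  gpa <- generalized_procrustes(dataset)
  shapes <- as_shape_matrix(gpa$aligned)
  pca <- fit_pca(shapes)
  fit_ids <- rec$specimen_id[!rec$posteriori_flag]
  post_ids <- rec$specimen_id[rec$posteriori_flag]
  fit_scores <- pca$scores[fit_ids, , drop = FALSE]
  fit_groups <- rec$group[match(fit_ids, rec$specimen_id)]
  if (is.null(n_pcs))
    n_pcs <- select_pc_count(fit_scores, fit_groups, k_max = k_max)
  cva <- fit_cva(fit_scores[, seq_len(n_pcs), drop = FALSE], fit_groups)
  cls <- jackknife_classification(fit_scores, fit_groups, n_pcs = n_pcs)
  post_cv <- if (length(post_ids))
    project_posteriori(cva, pca, shapes[post_ids, , drop = FALSE])
  else NULL
  typ <- if (!is.null(post_cv))
    typicality_probabilities(cva, post_cv, df_mode = df_mode)
  else typicality_probabilities(cva, cva$cv_scores, df_mode = df_mode)
  allo <- allometry_test(gpa$centroid_sizes[fit_ids], cva$cv_scores)
  extremes <- lapply(seq_len(ncol(cva$cv_scores)), function(ax) {
    rng <- range(cva$cv_scores[, ax])
    list(min = extreme_shape(pca, cva, ax, rng[1]),
         max = extreme_shape(pca, cva, ax, rng[2]))
  })
  names(extremes) <- colnames(cva$cv_scores)
  out <- structure(
    list(gpa = gpa, pca = pca, n_pcs = as.integer(n_pcs), cva = cva,
         classification = cls, posteriori_scores = post_cv,
         typicality = typ, allometry = allo, extremes = extremes,
         records = rec, subset = subset),
    class = "edj_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, t0)
  out
}

#' @export
print.edj_pipeline <- function(x, ...) {
  cat(sprintf("<edj_pipeline> subset=%s, %d specimens, %d PCs, %d groups\n",
              x$subset, nrow(x$pca$scores), x$n_pcs, length(x$cva$groups)))
  cat(sprintf("  CV%% variance: %s | overall jackknife accuracy %.1f%%\n",
              paste(sprintf("%.2f", x$cva$pct_variance), collapse = "/"),
              x$classification$overall_accuracy))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir, t0 = Sys.time()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  aligned <- as_shape_matrix(res$gpa$aligned)
  wcsv(data.frame(specimen_id = rownames(aligned), aligned,
                  check.names = FALSE), "aligned_coordinates.csv")
  wcsv(data.frame(specimen_id = names(res$gpa$centroid_sizes),
                  centroid_size = res$gpa$centroid_sizes),
       "centroid_sizes.csv")
  wcsv(data.frame(specimen_id = rownames(res$pca$scores), res$pca$scores,
                  check.names = FALSE), "pc_scores.csv")
  cv_all <- rbind(res$cva$cv_scores, res$posteriori_scores)
  wcsv(data.frame(specimen_id = rownames(cv_all), cv_all,
                  check.names = FALSE), "cv_scores.csv")
  wcsv(data.frame(group = res$classification$groups,
                  res$classification$counts, check.names = FALSE),
       "classification_frequencies.csv")
  wcsv(data.frame(group = res$classification$groups,
                  res$classification$percentages, check.names = FALSE),
       "classification_percentages.csv")
  wcsv(res$typicality, "typicality.csv")
  wcsv(res$allometry, "allometry.csv")
  ext <- do.call(rbind, lapply(names(res$extremes), function(ax)
    do.call(rbind, lapply(c("min", "max"), function(end) {
      m <- res$extremes[[ax]][[end]]
      data.frame(axis = ax, end = end, landmark_index = seq_len(nrow(m)),
                 x = m[, 1], y = m[, 2], z = m[, 3])
    }))))
  wcsv(ext, "extreme_shapes.csv")
  log <- list(
    subset = res$subset, n_specimens = nrow(res$pca$scores),
    n_pcs = res$n_pcs, groups = res$cva$groups,
    gpa_iterations = res$gpa$n_iterations,
    gpa_converged = res$gpa$converged,
    cv_pct_variance = round(res$cva$pct_variance, 4),
    overall_accuracy = res$classification$overall_accuracy,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the pipeline from a JSON configuration file
#'
#' The configuration names the landmark CSV, optional metadata CSV, the
#' molar-position subset, a fixed `n_pcs` or screening bound `k_max`, and
#' the output directory. Fields absent from the file keep the
#' [run_pipeline] defaults.
#'
#' @param config_path Path to a JSON file with fields `landmarks`,
#'   optional `metadata`, `subset`, `n_pcs`, `k_max`, `df_mode`,
#'   `out_dir`.
#' @return The `edj_pipeline` result (invisibly if `out_dir` is set).
#' @export
run_pipeline_config <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  if (is.null(cfg$landmarks)) stop("config must name a 'landmarks' CSV")
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p) || file.exists(p)) p
    else file.path(base, p)
  }
  dataset <- read_landmark_table(resolve(cfg$landmarks),
                                 metadata = resolve(cfg$metadata))
  run_pipeline(dataset,
               subset = cfg$subset %||% "all",
               n_pcs = cfg$n_pcs, k_max = cfg$k_max,
               df_mode = cfg$df_mode %||% "n_cv",
               out_dir = resolve(cfg$out_dir))
}
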