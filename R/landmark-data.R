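#' Landmark configuration for one specimen
#'
#' A `landmark_config` holds one specimen's ordered K x 3 coordinate matrix
#' together with the per-point landmark kind and the tooth side. The point
#' order is the homology order around the marginal ridge of the
#' enamel-dentine junction (EDJ): Protoconid, Metaconid, Entoconid,
#' Hypoconulid, Hypoconid, and back to the Protoconid, with semilandmarks
#' interleaved along the connecting ridge segments. The default EDJ scheme
#' has 5 fixed dentine-horn landmarks and 142 ridge semilandmarks (K = 147).
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param coords Numeric K x 3 matrix of coordinates (columns x, y, z), in
#'   arbitrary but dataset-consistent length units.
#' @param landmark_kind Character vector of length K with values `"fixed"`
#'   or `"semilandmark"`. Defaults to all `"fixed"`.
#' @param side One of `"left"`, `"right"`, `"unknown"`.
#' @return An object of class `landmark_config`.
#' @examples
#' tri <- landmark_config("t1", matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3))
#' centroid_size(tri)
#' @export
landmark_config <- function(specimen_id, coords,
                            landmark_kind = rep("fixed", nrow(coords)),
                            side = "unknown") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("'coords' must have 3 columns (x, y, z)")
  if (nrow(coords) < 3L)
    stop("a landmark configuration needs K >= 3 points")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in configuration '", specimen_id, "'")
  landmark_kind <- match.arg(landmark_kind, c("fixed", "semilandmark"),
                             several.ok = TRUE)
  if (length(landmark_kind) == 1L)
    landmark_kind <- rep(landmark_kind, nrow(coords))
  if (length(landmark_kind) != nrow(coords))
    stop("'landmark_kind' must have one entry per landmark")
  side <- match.arg(side, c("left", "right", "unknown"))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(specimen_id = as.character(specimen_id), coords = coords,
         landmark_kind = landmark_kind, side = side),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d points (%d fixed, %d semilandmarks), side=%s\n",
              x$specimen_id, nrow(x$coords),
              sum(x$landmark_kind == "fixed"),
              sum(x$landmark_kind == "semilandmark"), x$side))
  invisible(x)
}

#' Specimen metadata table constructor
#'
#' Builds the per-specimen record table that accompanies a set of landmark
#' configurations: group (geographic origin or species for the comparative
#' sample), site, molar position, side, whether the specimen is only
#' projected a posteriori (excluded from CVA fitting), and optional
#' per-observer molar-position calls.
#'
#' @param specimen_id Character vector, unique.
#' @param group Character vector of group labels.
#' @param site Character vector (defaults to `group`).
#' @param molar_position One of `"M1"`, `"M2"`, `"M3"`, `"unassigned"` per
#'   specimen.
#' @param side One of `"left"`, `"right"`, `"unknown"` per specimen.
#' @param posteriori_flag Logical; `TRUE` marks specimens excluded from CVA
#'   fitting and projected a posteriori.
#' @param observer1,observer2,observer3 Optional per-observer molar-position
#'   calls in `"M1"`, `"M2"`, `"M3"`, `"none"`.
#' @return A `data.frame` with one row per specimen.
#' @export
specimen_records <- function(specimen_id, group, site = group,
                             molar_position = "unassigned",
                             side = "unknown", posteriori_flag = FALSE,
                             observer1 = NA_character_,
                             observer2 = NA_character_,
                             observer3 = NA_character_) {
  n <- length(specimen_id)
  if (anyDuplicated(specimen_id))
    stop("duplicated specimen_id in metadata")
  rec <- data.frame(
    specimen_id = as.character(specimen_id),
    group = rep_len(as.character(group), n),
    site = rep_len(as.character(site), n),
    molar_position = rep_len(as.character(molar_position), n),
    side = rep_len(as.character(side), n),
    posteriori_flag = rep_len(as.logical(posteriori_flag), n),
    observer1 = rep_len(as.character(observer1), n),
    observer2 = rep_len(as.character(observer2), n),
    observer3 = rep_len(as.character(observer3), n),
    stringsAsFactors = FALSE)
  bad <- !rec$molar_position %in% c("M1", "M2", "M3", "unassigned")
  if (any(bad))
    stop("invalid molar_position: ", paste(unique(rec$molar_position[bad]),
                                           collapse = ", "))
  rec
}

#' Dataset of landmark configurations with specimen metadata
#'
#' Pairs a list of [landmark_config] objects with a metadata table from
#' [specimen_records]. All configurations must share K and the
#' landmark-kind pattern, and configurations and records must match
#' one-to-one on `specimen_id`.
#'
#' @param configurations List of [landmark_config] objects.
#' @param records Metadata `data.frame` as built by [specimen_records]. If
#'   omitted, a minimal record table with every specimen in group
#'   `"ungrouped"` is created.
#' @return An object of class `edj_dataset`.
#' @export
edj_dataset <- function(configurations, records = NULL) {
  stopifnot(is.list(configurations))
  ids <- vapply(configurations, function(cf) cf$specimen_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated specimen_id among configurations")
  names(configurations) <- ids
  if (length(configurations)) {
    ks <- vapply(configurations, function(cf) nrow(cf$coords), integer(1))
    if (length(unique(ks)) > 1L)
      stop("inconsistent landmark count across specimens: K in {",
           paste(sort(unique(ks)), collapse = ", "), "}")
    kinds <- vapply(configurations,
                    function(cf) paste(cf$landmark_kind, collapse = ""),
                    character(1))
    if (length(unique(kinds)) > 1L)
      stop("landmark_kind pattern differs across specimens")
  }
  if (is.null(records)) {
    records <- specimen_records(ids, group = "ungrouped",
                                side = vapply(configurations,
                                              function(cf) cf$side,
                                              character(1)))
  }
  if (!setequal(records$specimen_id, ids))
    stop("configurations and records disagree on specimen ids")
  records <- records[match(ids, records$specimen_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(configurations = configurations, records = records),
            class = "edj_dataset")
}

#' @export
print.edj_dataset <- function(x, ...) {
  k <- if (length(x$configurations)) nrow(x$configurations[[1]]$coords) else 0L
  cat(sprintf("<edj_dataset> %d specimens, K=%d landmarks\n",
              length(x$configurations), k))
  if (nrow(x$records))
    print(table(group = x$records$group))
  invisible(x)
}

#' @export
length.edj_dataset <- function(x) length(x$configurations)

# flatten a K x 3 coordinate matrix to (x1,y1,z1,x2,...) and back
flatten_coords <- function(m) as.vector(t(m))

unflatten_coords <- function(v) {
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Stack a dataset into an n x 3K shape matrix
#'
#' Each row is one specimen's coordinates flattened landmark-major
#' (x1, y1, z1, x2, ...), the vectorization used by the PCA and CVA stages.
#'
#' @param dataset An [edj_dataset] or a plain list of K x 3 matrices.
#' @return Numeric n x 3K matrix with specimen ids as row names.
#' @export
as_shape_matrix <- function(dataset) {
  mats <- if (inherits(dataset, "edj_dataset"))
    lapply(dataset$configurations, function(cf) cf$coords)
  else dataset
  out <- do.call(rbind, lapply(mats, flatten_coords))
  rownames(out) <- names(mats)
  out
}
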