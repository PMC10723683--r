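#' Read a long-format landmark coordinate table
#'
#' Reads specimen landmark coordinates from a long-format CSV with one row
#' per (specimen, landmark) pair — the canonical dialect for the 147-point
#' EDJ scheme. Required columns: `specimen_id`, `landmark_index` (1-based),
#' `x`, `y`, `z`; optional columns `landmark_kind` and `side` are carried
#' into the configurations. If a metadata file is supplied, its records are
#' attached; otherwise minimal records are synthesized.
#'
#' @param path Path to the CSV file.
#' @param metadata Optional path to a metadata CSV with columns
#'   `specimen_id`, `group`, and optionally `site`, `molar_position`,
#'   `side`, `posteriori_flag`, `observer1..3`.
#' @param dialect Named list overriding column names, e.g.
#'   `list(specimen_id = "id")`.
#' @return An [edj_dataset].
#' @export
read_landmark_table <- function(path, metadata = NULL, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- utils::modifyList(
    list(specimen_id = "specimen_id", landmark_index = "landmark_index",
         x = "x", y = "y", z = "z", landmark_kind = "landmark_kind",
         side = "side"),
    dialect)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(cols[c("specimen_id", "landmark_index", "x", "y", "z")])
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(edj_dataset(list()))
  for (cc in unlist(cols[c("x", "y", "z")])) {
    v <- tab[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric coordinate in column '", cc, "' at data row ",
             bad[1])
      tab[[cc]] <- vn
    }
  }
  key <- paste(tab[[cols$specimen_id]], tab[[cols$landmark_index]])
  if (anyDuplicated(key))
    stop("duplicate (specimen, landmark_index) pair at data row ",
         which(duplicated(key))[1])
  configs <- lapply(split(tab, tab[[cols$specimen_id]]), function(d) {
    d <- d[order(d[[cols$landmark_index]]), , drop = FALSE]
    idx <- d[[cols$landmark_index]]
    if (!identical(as.integer(idx), seq_len(nrow(d))))
      stop("specimen '", d[[cols$specimen_id]][1],
           "': landmark_index must be 1..K without gaps")
    kind <- if (cols$landmark_kind %in% names(d)) d[[cols$landmark_kind]]
            else rep("fixed", nrow(d))
    side <- if (cols$side %in% names(d)) d[[cols$side]][1] else "unknown"
    landmark_config(d[[cols$specimen_id]][1],
                    as.matrix(d[, unlist(cols[c("x", "y", "z")])]),
                    landmark_kind = kind, side = side)
  })
  # keep first-appearance order of specimens, not alphabetical split order
  configs <- configs[unique(tab[[cols$specimen_id]])]
  records <- if (!is.null(metadata)) read_specimen_metadata(metadata)
  edj_dataset(configs, records)
}

#' Write a dataset as a long-format landmark CSV
#'
#' Inverse of [read_landmark_table]: coordinates are written with full
#' double precision (17 significant digits) so that a read/write round trip
#' is the identity.
#'
#' @param dataset An [edj_dataset].
#' @param path Output CSV path.
#' @export
write_landmark_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "edj_dataset"))
  rows <- lapply(dataset$configurations, function(cf) {
    data.frame(specimen_id = cf$specimen_id,
               landmark_index = seq_len(nrow(cf$coords)),
               x = cf$coords[, 1], y = cf$coords[, 2], z = cf$coords[, 3],
               landmark_kind = cf$landmark_kind, side = cf$side,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (cc in c("x", "y", "z")) tab[[cc]] <- sprintf("%.17g", tab[[cc]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read specimen metadata
#'
#' @param path CSV with columns `specimen_id`, `group` and optionally
#'   `site`, `molar_position`, `side`, `posteriori_flag`, `observer1..3`.
#' @return A records `data.frame` (see [specimen_records]).
#' @export
read_specimen_metadata <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "group") %in% names(m)))
    stop("metadata needs at least columns specimen_id and group")
  grab <- function(col, default) if (col %in% names(m)) m[[col]] else default
  specimen_records(
    m$specimen_id, m$group, site = grab("site", m$group),
    molar_position = grab("molar_position", "unassigned"),
    side = grab("side", "unknown"),
    posteriori_flag = grab("posteriori_flag", FALSE),
    observer1 = grab("observer1", NA_character_),
    observer2 = grab("observer2", NA_character_),
    observer3 = grab("observer3", NA_character_))
}

#' Read a TPS landmark file
#'
#' Parses the `LM3=` dialect of the TPS interchange format: each record is
#' an `LM3=K` line, K coordinate lines of three numbers, and an optional
#' `ID=` line. Records lacking an ID are assigned
#' `specimen_<ordinal>`.
#'
#' @param path TPS file path.
#' @return An [edj_dataset].
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  configs <- list()
  i <- 1L; ordinal <- 0L
  while (i <= length(lines)) {
    if (!grepl("^LM3=", lines[i], ignore.case = TRUE))
      stop("expected LM3= record at line ", i, ", got: ", lines[i])
    k <- as.integer(sub("^LM3=", "", lines[i], ignore.case = TRUE))
    if (is.na(k) || k < 1L) stop("bad LM3 count at line ", i)
    if (i + k > length(lines))
      stop("LM3=", k, " but file ends after ",
           length(lines) - i, " coordinate lines")
    coord_lines <- lines[(i + 1L):(i + k)]
    vals <- lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:]]+")[[1]]))
      if (length(v) != 3L || anyNA(v))
        stop("LM3 count mismatch: expected 3 numeric coordinates, got '",
             l, "'")
      v
    })
    i <- i + k + 1L
    id <- NULL
    while (i <= length(lines) && !grepl("^LM3=", lines[i],
                                        ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    ordinal <- ordinal + 1L
    if (is.null(id)) id <- sprintf("specimen_%d", ordinal)
    configs[[length(configs) + 1L]] <-
      landmark_config(id, do.call(rbind, vals))
  }
  edj_dataset(configs)
}

#' Write a dataset as a TPS file
#'
#' @param dataset An [edj_dataset].
#' @param path Output path.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "edj_dataset"))
  con <- file(path, "w"); on.exit(close(con))
  for (cf in dataset$configurations) {
    writeLines(sprintf("LM3=%d", nrow(cf$coords)), con)
    writeLines(apply(cf$coords, 1, function(p)
      paste(sprintf("%.17g", p), collapse = " ")), con)
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
  }
  invisible(NULL)
}

#' Mirror a left configuration into a right antimere
#'
#' Reflects the configuration through the plane of the first coordinate
#' axis (x -> -x) so that left molars can be analyzed jointly with right
#' ones; after Procrustes superimposition any single-axis reflection is
#' equivalent. Point order, centroid size and all inter-point distances
#' are unchanged; the side label becomes `"right"`.
#'
#' @param config A [landmark_config] with `side = "left"`.
#' @param force Mirror even if the side is not `"left"` (the side label
#'   then flips right to left, or stays `"unknown"`).
#' @return The mirrored [landmark_config].
#' @export
mirror_configuration <- function(config, force = FALSE) {
  stopifnot(inherits(config, "landmark_config"))
  if (config$side != "left" && !force)
    stop("refusing to mirror a non-left configuration (side=",
         config$side, "); use force=TRUE to override")
  out <- config
  out$coords[, 1] <- -out$coords[, 1]
  out$side <- switch(config$side, left = "right", right = "left", "unknown")
  out
}

#' Mirror all left specimens of a dataset
#'
#' @param dataset An [edj_dataset].
#' @return The dataset with every `side == "left"` configuration mirrored
#'   (all teeth virtually right antimeres).
#' @export
mirror_lefts <- function(dataset) {
  stopifnot(inherits(dataset, "edj_dataset"))
  dataset$configurations <- lapply(dataset$configurations, function(cf)
    if (cf$side == "left") mirror_configuration(cf) else cf)
  dataset$records$side[dataset$records$side == "left"] <- "right"
  dataset
}

#' Majority-consensus molar position
#'
#' Combines up to three observers' molar-position calls by majority rule:
#' a position supported by at least two observers wins; with no majority
#' the specimen stays `"unassigned"` (such specimens enter only the
#' all-positions analysis). The call order is irrelevant.
#'
#' @param observer_calls Character vector of 1-3 calls in
#'   `"M1"`, `"M2"`, `"M3"`, `"none"` (`NA` treated as `"none"`).
#' @return A list with `label` (the consensus position or `"unassigned"`)
#'   and `support` (number of agreeing calls; the largest single count when
#'   there is no majority).
#' @export
consensus_molar_position <- function(observer_calls) {
  if (length(observer_calls) == 0L) stop("empty observer call list")
  calls <- as.character(observer_calls)
  calls[is.na(calls)] <- "none"
  bad <- setdiff(calls, c("M1", "M2", "M3", "none"))
  if (length(bad)) stop("invalid call(s): ", paste(bad, collapse = ", "))
  pos <- calls[calls != "none"]
  if (!length(pos)) return(list(label = "unassigned", support = 0L))
  tab <- table(pos)
  top <- max(tab)
  if (top >= 2L) {
    winners <- names(tab)[tab == top]
    # 2-2 cannot happen with <=3 calls, but keep deterministic anyway
    list(label = sort(winners)[1], support = as.integer(top))
  } else {
    list(label = "unassigned", support = as.integer(top))
  }
}

#' Apply consensus molar positions to a metadata table
#'
#' Fills `molar_position` from the `observer1..3` columns by
#' [consensus_molar_position], leaving rows without observer calls
#' untouched.
#'
#' @param records A records `data.frame`.
#' @return The updated records with columns `molar_position` and
#'   `position_support`.
#' @export
assign_molar_positions <- function(records) {
  obs <- records[, c("observer1", "observer2", "observer3"), drop = FALSE]
  records$position_support <- NA_integer_
  for (i in seq_len(nrow(records))) {
    calls <- unlist(obs[i, ])
    calls <- calls[!is.na(calls)]
    if (!length(calls)) next
    cns <- consensus_molar_position(calls)
    records$molar_position[i] <- cns$label
    records$position_support[i] <- cns$support
  }
  records
}

#' Subset a dataset
#'
#' @param dataset An [edj_dataset].
#' @param ids Specimen ids to keep, in dataset order.
#' @return The reduced [edj_dataset].
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "edj_dataset"))
  miss <- setdiff(ids, names(dataset$configurations))
  if (length(miss)) stop("unknown specimen id(s): ",
                         paste(miss, collapse = ", "))
  keep <- names(dataset$configurations) %in% ids
  edj_dataset(dataset$configurations[keep],
              dataset$records[dataset$records$specimen_id %in% ids, ,
                              drop = FALSE])
}
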