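#' Per-protein multiple sequence alignment container
#'
#' Aligned residue strings over the 20 amino acids plus `-` (gap) and `X`
#' (unknown/uncovered), one per sample, all of equal length, with each
#' sample classed as `modern` (reference individuals translated from
#' genomes) or `fossil` (consensus sequences reconstructed from ancient
#' peptides). Columns are 1-based on the declared reference coordinate
#' system (the *Pongo abelii* canonical sequence in the intended use).
#'
#' @param protein_id Protein name (e.g. `"AMBN"`, `"ENAM"`).
#' @param sequences Named character vector of aligned sequences.
#' @param sample_class Named character vector (`"modern"`/`"fossil"`),
#'   names matching `sequences`; defaults to all modern.
#' @return A `protein_alignment` object.
#' @export
protein_alignment <- function(protein_id, sequences, sample_class = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by sample id")
  sequences <- toupper(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("aligned sequences differ in length: ",
         paste(L, collapse = ", "))
  if (is.null(sample_class))
    sample_class <- stats::setNames(rep("modern", length(sequences)),
                                    names(sequences))
  miss <- setdiff(names(sequences), names(sample_class))
  if (length(miss)) stop("sample_class missing for: ",
                         paste(miss, collapse = ", "))
  sample_class <- sample_class[names(sequences)]
  if (!all(sample_class %in% c("modern", "fossil")))
    stop("sample_class values must be 'modern' or 'fossil'")
  structure(list(protein_id = protein_id, sequences = sequences,
                 sample_class = sample_class, length = L),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %s: %d samples x %d columns (%d fossil)\n",
              x$protein_id, length(x$sequences), x$length,
              sum(x$sample_class == "fossil")))
  invisible(x)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- names(aln$sequences)
  m
}

matrix_to_aln <- function(m, aln) {
  aln$sequences <- stats::setNames(apply(m, 1, paste, collapse = ""),
                                   rownames(m))
  aln
}

#' Reconstruct a consensus protein sequence from aligned peptide fragments
#'
#' Given one sample's peptide fragments already placed on the reference
#' coordinate system (each fragment carries a 1-based `start`), every
#' reference column takes the majority residue among the fragments
#' covering it. Ties are broken toward the residue of the
#' highest-intensity covering fragment, then lexicographically; columns
#' covered by no fragment become `X`.
#'
#' @param fragments `data.frame` with columns `sequence`, `start`, and
#'   optionally `intensity` (default 0).
#' @param ref_length Length L of the reference sequence.
#' @param protein_id,sample_id Labels carried into the result.
#' @return A `consensus_sequence`: list with `protein_id`, `sample_id`,
#'   `sequence` (length-L string), `support` (covering-fragment count per
#'   column), `covered` (number of non-gap, non-X positions).
#' @export
reconstruct_consensus <- function(fragments, ref_length,
                                  protein_id = "protein",
                                  sample_id = "sample") {
  if (is.null(fragments$intensity))
    fragments$intensity <- rep(0, nrow(fragments))
  res <- rep("X", ref_length)
  support <- integer(ref_length)
  cover <- vector("list", ref_length)
  for (i in seq_len(nrow(fragments))) {
    sq <- strsplit(toupper(fragments$sequence[i]), "")[[1]]
    st <- fragments$start[i]
    if (st < 1L || st + length(sq) - 1L > ref_length)
      stop("fragment ", i, " overruns the reference (start=", st,
           ", length=", length(sq), ", L=", ref_length, ")")
    for (j in seq_along(sq)) {
      pos <- st + j - 1L
      cover[[pos]] <- rbind(cover[[pos]],
                            data.frame(res = sq[j],
                                       intensity = fragments$intensity[i]))
    }
  }
  for (pos in seq_len(ref_length)) {
    cv <- cover[[pos]]
    if (is.null(cv)) next
    support[pos] <- nrow(cv)
    tab <- table(cv$res)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) {
      res[pos] <- winners
    } else {
      top <- cv[cv$res %in% winners, ]
      best <- top$res[order(-top$intensity, top$res)][1]
      res[pos] <- best
    }
  }
  structure(list(protein_id = protein_id, sample_id = sample_id,
                 sequence = paste(res, collapse = ""), support = support,
                 covered = sum(res != "X" & res != "-")),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("<consensus_sequence> %s/%s: %d of %d positions covered\n",
              x$sample_id, x$protein_id, x$covered, nchar(x$sequence)))
  invisible(x)
}

#' Amino-acid coverage per sample and protein
#'
#' @param consensuses List of `consensus_sequence` objects (any mix of
#'   samples and proteins).
#' @return A `data.frame` sample x protein of covered amino-acid counts
#'   (wide, with a `total` column).
#' @export
coverage_per_protein <- function(consensuses) {
  long <- do.call(rbind, lapply(consensuses, function(cs)
    data.frame(sample_id = cs$sample_id, protein_id = cs$protein_id,
               covered = cs$covered, stringsAsFactors = FALSE)))
  wide <- stats::reshape(long, idvar = "sample_id",
                         timevar = "protein_id", direction = "wide")
  names(wide) <- sub("^covered\\.", "", names(wide))
  wide[is.na(wide)] <- 0L
  wide$total <- as.integer(rowSums(wide[, -1, drop = FALSE]))
  rownames(wide) <- NULL
  wide
}

#' Collapse the isobaric isoleucine/leucine ambiguity by parsimony
#'
#' Isoleucine and leucine have identical mass and cannot be distinguished
#' by the mass spectrometry producing the fossil sequences. For every
#' alignment column covered by at least one fossil sample with an I or L:
#' if all modern samples carry the same one of the two residues there,
#' the fossil I/L residues are switched to it; if both I and L occur
#' among the modern samples, every sample's I/L residue at that column is
#' set to L. Columns without fossil I/L coverage, and residues other than
#' I/L, are never touched, so the operation is idempotent.
#'
#' @param alignment A [protein_alignment].
#' @return The collapsed [protein_alignment].
#' @export
collapse_isobaric <- function(alignment) {
  stopifnot(inherits(alignment, "protein_alignment"))
  m <- aln_matrix(alignment)
  fossil <- alignment$sample_class == "fossil"
  modern <- !fossil
  for (col in seq_len(ncol(m))) {
    fres <- m[fossil, col]
    if (!any(fres %in% c("I", "L"))) next
    mres <- m[modern, col]
    m_il <- intersect(unique(mres), c("I", "L"))
    if (length(m_il) == 1L) {
      # all modern that have I or L agree; switch fossil I/L to match
      m[fossil & m[, col] %in% c("I", "L"), col] <- m_il
    } else if (length(m_il) == 2L) {
      m[m[, col] %in% c("I", "L"), col] <- "L"
    }
    # modern have neither I nor L: no parsimony call, leave unchanged
  }
  matrix_to_aln(m, alignment)
}

#' Concatenate per-protein alignments into a supermatrix
#'
#' Appends alignment columns in the given protein order over a common
#' sample universe; samples absent from a protein are gap-filled. The
#' partition table records the 1-based inclusive column range of each
#' protein, ready for RAxML-style partition files and NEXUS charsets.
#'
#' @param alignments List of [protein_alignment] objects with distinct
#'   protein ids.
#' @param samples Sample universe (default: union over alignments, in
#'   first-appearance order).
#' @return A list with `alignment` (a [protein_alignment] with id
#'   `"concatenated"`) and `partitions` (`data.frame` protein/start/end).
#' @export
concatenate_alignments <- function(alignments, samples = NULL) {
  ids <- vapply(alignments, function(a) a$protein_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ", ids[duplicated(ids)][1])
  if (is.null(samples))
    samples <- unique(unlist(lapply(alignments,
                                    function(a) names(a$sequences))))
  seqs <- stats::setNames(rep("", length(samples)), samples)
  classes <- stats::setNames(rep(NA_character_, length(samples)), samples)
  parts <- data.frame(protein = character(0), start = integer(0),
                      end = integer(0))
  pos <- 0L
  for (a in alignments) {
    block <- vapply(samples, function(s) {
      if (s %in% names(a$sequences)) a$sequences[[s]]
      else strrep("-", a$length)
    }, character(1))
    seqs <- paste0(seqs, block)
    names(seqs) <- samples
    for (s in intersect(samples, names(a$sequences)))
      if (is.na(classes[[s]])) classes[[s]] <- a$sample_class[[s]]
    parts <- rbind(parts, data.frame(protein = a$protein_id,
                                     start = pos + 1L,
                                     end = pos + a$length))
    pos <- pos + a$length
  }
  classes[is.na(classes)] <- "modern"
  list(alignment = protein_alignment("concatenated", seqs, classes),
       partitions = parts)
}

#' Split a concatenated alignment back into its partitions
#'
#' Round-trip inverse of [concatenate_alignments] (gap-only rows for
#' samples absent from a protein are retained).
#'
#' @param concat Result of [concatenate_alignments] (or an alignment plus
#'   a `partitions` table).
#' @param partitions Partition table when `concat` is a bare alignment.
#' @return Named list of [protein_alignment] objects.
#' @export
split_alignment <- function(concat, partitions = NULL) {
  if (is.null(partitions)) { partitions <- concat$partitions
                             concat <- concat$alignment }
  out <- lapply(seq_len(nrow(partitions)), function(i)
    protein_alignment(partitions$protein[i],
                      substr(concat$sequences, partitions$start[i],
                             partitions$end[i]),
                      concat$sample_class))
  stats::setNames(out, partitions$protein)
}

#' Report single amino acid polymorphisms within a clade
#'
#' Scans each alignment for columns where the focal clade's samples show
#' two or more distinct non-gap, non-X residues (run [collapse_isobaric]
#' first so I/L noise is not reported). For each such column the report
#' gives the variant residues and a per-group frequency table of
#' per-sample calls; uncovered samples are missing (the black cells of a
#' variant heat map).
#'
#' @param alignments List of [protein_alignment] objects.
#' @param clade_samples Sample ids forming the focal clade.
#' @param group_labels Named character vector mapping those sample ids to
#'   groups (species/site); defaults to one group `"clade"`.
#' @return A `data.frame` with columns `protein`, `column`, `variants`,
#'   `group`, `residue`, `count` (long format; zero rows when the clade
#'   is invariant).
#' @export
find_saps <- function(alignments, clade_samples, group_labels = NULL) {
  if (inherits(alignments, "protein_alignment"))
    alignments <- list(alignments)
  if (is.null(group_labels))
    group_labels <- stats::setNames(rep("clade", length(clade_samples)),
                                    clade_samples)
  rows <- list()
  for (a in alignments) {
    miss <- setdiff(clade_samples, names(a$sequences))
    if (length(miss) == length(clade_samples))
      stop("none of the clade samples are in alignment ", a$protein_id)
    m <- aln_matrix(a)[intersect(clade_samples, names(a$sequences)), ,
                       drop = FALSE]
    for (col in seq_len(ncol(m))) {
      res <- m[, col]
      obs <- res[!res %in% c("-", "X")]
      vars <- sort(unique(obs))
      if (length(vars) < 2L) next
      grp <- group_labels[rownames(m)][!res %in% c("-", "X")]
      tab <- table(group = grp, residue = obs)
      for (g in rownames(tab)) for (v in colnames(tab))
        if (tab[g, v] > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            protein = a$protein_id, column = col,
            variants = paste(vars, collapse = "/"),
            group = g, residue = v, count = as.integer(tab[g, v]),
            stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(0), column = integer(0),
                      variants = character(0), group = character(0),
                      residue = character(0), count = integer(0)))
  do.call(rbind, rows)
}

#' Write an alignment (FASTA, relaxed PHYLIP, or NEXUS with charsets)
#'
#' FASTA goes through Biostrings; NEXUS uses ape's protein NEXUS writer
#' with an appended `sets` block of per-protein charsets when a partition
#' table is supplied; relaxed PHYLIP (name, whitespace, full sequence) is
#' written directly. A RAxML-style partition file (`PROT, name = a-b`)
#' can be written alongside.
#'
#' @param alignment A [protein_alignment].
#' @param path Output file path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param partitions Optional partition table (see
#'   [concatenate_alignments]).
#' @param partition_path Optional path for the RAxML-style partition
#'   file.
#' @export
write_alignment <- function(alignment, path,
                            format = c("fasta", "phylip", "nexus"),
                            partitions = NULL, partition_path = NULL) {
  stopifnot(inherits(alignment, "protein_alignment"))
  format <- match.arg(format)
  seqs <- alignment$sequences
  if (format == "fasta") {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
    } else {
      writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
    }
  } else if (format == "phylip") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(" %d %d", length(seqs), alignment$length), con)
    writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  } else {
    if (!requireNamespace("ape", quietly = TRUE))
      stop("writing NEXUS requires the 'ape' package")
    ape::write.nexus.data(strsplit(seqs, ""), path, format = "protein",
                          interleaved = FALSE)
    if (!is.null(partitions)) {
      sets <- c("begin sets;",
                sprintf("  charset %s = %d-%d;", partitions$protein,
                        partitions$start, partitions$end),
                "end;")
      cat(paste0(sets, "\n"), file = path, append = TRUE, sep = "")
    }
  }
  if (!is.null(partition_path) && !is.null(partitions))
    writeLines(sprintf("PROT, %s = %d-%d", partitions$protein,
                       partitions$start, partitions$end), partition_path)
  invisible(NULL)
}

#' Read a protein alignment from FASTA or NEXUS
#'
#' @param path Input file.
#' @param format `"fasta"` or `"nexus"`.
#' @param protein_id Label for the resulting alignment.
#' @param sample_class Optional class vector (see [protein_alignment]).
#' @return A [protein_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "nexus"),
                           protein_id = "protein", sample_class = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readAAStringSet(path)
      seqs <- stats::setNames(as.character(ss), names(ss))
    } else {
      lines <- readLines(path)
      hdr <- grepl("^>", lines)
      idx <- cumsum(hdr)
      seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                     collapse = "")
      names(seqs) <- sub("^>", "", lines[hdr])
    }
  } else {
    if (!requireNamespace("ape", quietly = TRUE))
      stop("reading NEXUS requires the 'ape' package")
    lst <- ape::read.nexus.data(path)
    seqs <- vapply(lst, function(x) paste(toupper(x), collapse = ""),
                   character(1))
  }
  protein_alignment(protein_id, seqs, sample_class)
}
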