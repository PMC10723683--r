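set.seed(505)

toy_evidence_file <- function(path) {
  writeLines(c(
    paste("Sequence", "Proteins", "Modifications", "Intensity", "Raw file",
          "Reverse", "Potential contaminant", sep = "\t"),
    paste("PEPTIDENQ", "AMBN", "2 Deamidation (NQ)", "100", "s1", "", "",
          sep = "\t"),
    paste("AQRK", "ENAM", "1 Orn conversion (R)", "50", "s1", "", "",
          sep = "\t"),
    paste("GGSSEEK", "MMP20", "Unmodified", "10", "s1", "", "",
          sep = "\t"),
    paste("DECOYPEP", "REV__AMBN", "Unmodified", "10", "s1", "+", "",
          sep = "\t"),
    paste("KERATIN", "CON__K2C1", "Unmodified", "10", "s1", "", "+",
          sep = "\t")), path)
  path
}

test_that("evidence parsing computes residue counts and drops decoys", {
  f <- toy_evidence_file(withr::local_tempfile(fileext = ".txt"))
  ev <- parse_evidence(f)
  expect_identical(nrow(ev), 3L)          # reverse + contaminant removed
  expect_identical(ev$n_NQ, c(2L, 1L, 0L))
  expect_identical(ev$n_deamidated, c(2L, 0L, 0L))
  expect_identical(ev$n_R, c(0L, 1L, 0L))
  expect_identical(ev$n_arg_orn, c(0L, 1L, 0L))
  writeLines("Sequence\tProteins", f)
  expect_error(parse_evidence(f), "missing required column")
})

test_that("deamidation rate matches hand-computed weighted fractions", {
  rec <- data.frame(n_NQ = c(2L, 2L), n_deamidated = c(1L, 2L),
                    n_R = 0L, n_arg_orn = 0L, intensity = c(2, 1))
  expect_equal(deamidation_rate(rec),
               100 * (2 * 1 + 1 * 2) / (2 * 2 + 1 * 2), tolerance = 1e-12)
  all_deam <- data.frame(n_NQ = c(3L, 1L), n_deamidated = c(3L, 1L),
                         n_R = 0L, n_arg_orn = 0L, intensity = c(1, 9))
  expect_equal(deamidation_rate(all_deam), 100)
  none <- all_deam; none$n_deamidated <- 0L
  expect_equal(deamidation_rate(none), 0)
  no_nq <- data.frame(n_NQ = 0L, n_deamidated = 0L, n_R = 1L,
                      n_arg_orn = 0L, intensity = 1)
  expect_warning(expect_true(is.na(deamidation_rate(no_nq))), "undefined")
})

test_that("Arg->Orn ratio matches hand computation and edge cases", {
  rec <- data.frame(n_NQ = 0L, n_deamidated = 0L, n_R = c(1L, 1L),
                    n_arg_orn = c(0L, 1L), intensity = c(1, 3))
  expect_equal(arg_orn_ratio(rec), 3 / 4, tolerance = 1e-12)
  expect_equal(arg_orn_ratio(transform(rec, n_arg_orn = c(0L, 0L))), 0)
  expect_equal(arg_orn_ratio(transform(rec, n_arg_orn = c(1L, 1L))), 1)
})

test_that("damage rates are intensity-scale invariant and reduce to unweighted", {
  ev <- simulate_evidence(n_samples = 1, peptides_per_sample = 80,
                          deamidation_prob = 0.7, orn_prob = 0.2,
                          seed = 6)$records
  r1 <- deamidation_rate(ev)
  ev2 <- ev; ev2$intensity <- ev2$intensity * 1e3
  expect_equal(deamidation_rate(ev2), r1, tolerance = 1e-9)
  ev3 <- ev; ev3$intensity <- 5
  expect_equal(deamidation_rate(ev3),
               deamidation_rate(ev, weighting = "unweighted"),
               tolerance = 1e-9)
  expect_equal(arg_orn_ratio(ev3),
               arg_orn_ratio(ev, weighting = "unweighted"),
               tolerance = 1e-9)
})

test_that("simulated damage probabilities are recovered", {
  ev <- simulate_evidence(n_samples = 1, peptides_per_sample = 500,
                          deamidation_prob = 0.9, orn_prob = 0.15,
                          seed = 10)
  # the recovery claim is about binomial error, so use the unweighted
  # estimator (intensity weighting adds lognormal-weight variance)
  expect_lte(abs(deamidation_rate(ev$records, "unweighted") - 90), 2)
  expect_lte(abs(arg_orn_ratio(ev$records, "unweighted") - 0.15), 0.05)
  # file round trip and determinism
  f <- withr::local_tempfile(fileext = ".txt")
  ev1 <- simulate_evidence(2, 30, 0.8, 0.1, path = f, seed = 4)
  parsed <- parse_evidence(f)
  expect_equal(parsed$n_deamidated, ev1$records$n_deamidated)
  expect_equal(parsed$intensity, ev1$records$intensity, tolerance = 1e-6)
  ev2 <- simulate_evidence(2, 30, 0.8, 0.1, seed = 4)
  expect_identical(ev1$records, ev2$records)
})

test_that("consensus reconstruction follows majority then intensity", {
  frags <- data.frame(sequence = c("SSK", "SSK", "GSK"),
                      start = c(1, 1, 1), intensity = c(1, 1, 5))
  cs <- reconstruct_consensus(frags, ref_length = 5)
  expect_identical(substr(cs$sequence, 1, 3), "SSK")   # S beats G 2:1
  expect_identical(substr(cs$sequence, 4, 5), "XX")
  expect_identical(cs$covered, 3L)
  # tie at a column goes to the higher-intensity fragment's residue
  tie <- data.frame(sequence = c("A", "V"), start = 1,
                    intensity = c(1, 2))
  expect_identical(reconstruct_consensus(tie, 1)$sequence, "V")
  # and lexicographic when intensities tie too
  tie2 <- data.frame(sequence = c("V", "A"), start = 1, intensity = 1)
  expect_identical(reconstruct_consensus(tie2, 1)$sequence, "A")
  none <- reconstruct_consensus(
    data.frame(sequence = character(0), start = integer(0)), 4)
  expect_identical(none$sequence, "XXXX")
  expect_identical(none$covered, 0L)
  expect_error(reconstruct_consensus(
    data.frame(sequence = "AAAA", start = 3), 5), "overruns")
})

test_that("coverage counts unions of fragments per protein", {
  a <- reconstruct_consensus(
    data.frame(sequence = c(strrep("A", 10), strrep("G", 16)),
               start = c(1, 5)), 20, "AMBN", "s1")
  expect_identical(a$covered, 20L)
  b <- reconstruct_consensus(
    data.frame(sequence = c("AAAAA", "GGGGG"), start = c(1, 11)), 15,
    "ENAM", "s1")
  expect_identical(b$covered, 10L)
  z <- reconstruct_consensus(
    data.frame(sequence = character(0), start = integer(0)), 9,
    "MMP20", "s2")
  cov <- coverage_per_protein(list(a, b, z))
  expect_identical(cov$AMBN[cov$sample_id == "s1"], 20L)
  expect_identical(cov$total[cov$sample_id == "s1"], 30L)
  expect_identical(cov$total[cov$sample_id == "s2"], 0L)
})

il_alignment <- function() {
  protein_alignment(
    "AMBN",
    c(mod1 = "LAVKL", mod2 = "LAVKI", mod3 = "LAVKL",
      fos1 = "IAXKI", fos2 = "XAVKX"),
    c(mod1 = "modern", mod2 = "modern", mod3 = "modern",
      fos1 = "fossil", fos2 = "fossil"))
}

test_that("isobaric I/L collapsing applies both branches of the rule", {
  col <- collapse_isobaric(il_alignment())
  # column 1: modern all L, fossil I -> fossil switched to L
  expect_identical(substr(col$sequences[["fos1"]], 1, 1), "L")
  # column 5: both I and L among modern -> everyone L
  expect_identical(unique(substr(col$sequences[c("mod2", "fos1")], 5, 5)),
                   "L")
  # untouched residues and uncovered cells stay as they were
  expect_identical(substr(col$sequences[["fos2"]], 1, 1), "X")
  expect_identical(substr(col$sequences[["fos1"]], 2, 4), "AXK")
  # idempotence
  col2 <- collapse_isobaric(col)
  expect_identical(col2$sequences, col$sequences)
  # no fossil-covered column retains both I and L
  m <- do.call(rbind, strsplit(col$sequences, ""))
  for (j in seq_len(ncol(m)))
    if (any(m[4:5, j] %in% c("I", "L")))
      expect_lt(length(intersect(unique(m[, j]), c("I", "L"))), 2L)
})

test_that("columns without fossil I/L coverage are never modified", {
  aln <- protein_alignment(
    "ENAM", c(mod = "ILGA", fos = "XXGA"),
    c(mod = "modern", fos = "fossil"))
  out <- collapse_isobaric(aln)
  expect_identical(out$sequences, aln$sequences)
})

test_that("concatenation builds partitions, gap-fills, and round-trips", {
  a1 <- protein_alignment("AMBN",
                          c(s1 = strrep("A", 10), s2 = strrep("C", 10)),
                          c(s1 = "modern", s2 = "fossil"))
  a2 <- protein_alignment("ENAM", c(s1 = strrep("D", 15)),
                          c(s1 = "modern"))
  cc <- concatenate_alignments(list(a1, a2))
  expect_identical(cc$alignment$length, 25L)
  expect_identical(cc$partitions$start, c(1L, 11L))
  expect_identical(cc$partitions$end, c(10L, 25L))
  expect_identical(substr(cc$alignment$sequences[["s2"]], 11, 25),
                   strrep("-", 15))
  back <- split_alignment(cc)
  expect_identical(back$AMBN$sequences, a1$sequences)
  expect_identical(substr(back$ENAM$sequences[["s1"]], 1, 15),
                   a2$sequences[["s1"]])
  expect_error(concatenate_alignments(list(a1, a1)), "duplicate")
})

test_that("FASTA, PHYLIP and NEXUS writers emit readable files", {
  skip_if_not_installed("Biostrings")
  skip_if_not_installed("ape")
  cc <- concatenate_alignments(list(
    protein_alignment("AMBN", c(s1 = "PEPTIDE", s2 = "PEPTIDE")),
    protein_alignment("ENAM", c(s1 = "WAGKLM", s2 = "WAGRLM"))))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(cc$alignment, fa, "fasta")
  expect_identical(read_alignment(fa, "fasta")$sequences,
                   cc$alignment$sequences)
  nx <- withr::local_tempfile(fileext = ".nex")
  pf <- withr::local_tempfile(fileext = ".txt")
  write_alignment(cc$alignment, nx, "nexus", partitions = cc$partitions,
                  partition_path = pf)
  expect_identical(read_alignment(nx, "nexus")$sequences,
                   cc$alignment$sequences)
  expect_true(any(grepl("charset AMBN = 1-7", readLines(nx))))
  expect_identical(readLines(pf),
                   c("PROT, AMBN = 1-7", "PROT, ENAM = 8-13"))
  ph <- withr::local_tempfile(fileext = ".phy")
  write_alignment(cc$alignment, ph, "phylip")
  lines <- readLines(ph)
  expect_identical(lines[1], " 2 13")
  expect_match(lines[2], "^s1  PEPTIDEWAGKLM$")
})

test_that("SAP detection reports planted polymorphisms and nothing else", {
  # invariant alignment -> empty report
  inv <- protein_alignment("AMTN", c(a = "AAAA", b = "AAAA", c = "AA-A"))
  expect_identical(nrow(find_saps(inv, c("a", "b", "c"))), 0L)
  # planted D/E polymorphism at reference position 174
  L <- 180
  base <- strrep("G", L)
  seqs <- c(py1 = base, py2 = base, ab1 = base, fos = base)
  substr(seqs[["py1"]], 174, 174) <- "D"
  substr(seqs[["py2"]], 174, 174) <- "D"
  substr(seqs[["ab1"]], 174, 174) <- "E"
  substr(seqs[["fos"]], 174, 174) <- "E"
  aln <- protein_alignment("AMBN", seqs,
                           c(py1 = "modern", py2 = "modern",
                             ab1 = "modern", fos = "fossil"))
  rep <- find_saps(aln, names(seqs),
                   group_labels = c(py1 = "pygmaeus", py2 = "pygmaeus",
                                    ab1 = "abelii", fos = "fossil"))
  expect_identical(unique(rep$column), 174L)
  expect_identical(unique(rep$variants), "D/E")
  expect_identical(rep$count[rep$group == "pygmaeus" & rep$residue == "D"],
                   2L)
  expect_identical(rep$count[rep$group == "fossil" & rep$residue == "E"],
                   1L)
  # variation only via gaps/unknowns is not a SAP
  gappy <- protein_alignment("ALB", c(a = "A-A", b = "AXA", c = "AAA"))
  expect_identical(nrow(find_saps(gappy, c("a", "b", "c"))), 0L)
  expect_error(find_saps(aln, c("nobody")), "none of the clade")
})
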