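test_that("GENCODE-style headers are parsed into UTR5/CDS/UTR3 substrings", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(
    ">ENST0A|GENEA|misc|UTR5:1-3|CDS:4-9|UTR3:10-12|",
    "AAAATGGCCTTT",
    ">ENST0B|GENEB|CDS:1-6|",
    "ATGGCC"), fa)
  ts <- readTranscriptReference(fa)
  expect_s4_class(ts, "TranscriptSet")
  expect_identical(transcriptId(ts), c("ENST0A", "ENST0B"))
  expect_identical(as.character(cdsSeq(ts)[["ENST0A"]]), "ATGGCC")
  expect_identical(as.character(utr5Seq(ts)[["ENST0A"]]), "AAA")
  expect_identical(as.character(utr3Seq(ts)[["ENST0A"]]), "TTT")
  expect_identical(geneId(ts), c("GENEA", "GENEB"))
  expect_identical(as.character(utr5Seq(ts)[["ENST0B"]]), "")
})

test_that("records with absent or frame-breaking CDS are dropped, with a count", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(
    ">T1|G1|CDS:1-6|", "ATGGCC",
    ">T2|G2|CDS:1-5|", "ATGGC",       # length 5, not a codon multiple
    ">T3|G3|UTR5:1-2|", "AATTT",      # no CDS at all
    ">T4|G4|CDS:1-3|", "ATG"), fa)
  expect_message(ts <- readTranscriptReference(fa), "2 record")
  expect_identical(transcriptId(ts), c("T1", "T4"))
})

test_that("malformed headers are skipped with a warning, not fatally", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(
    ">T1|G1|CDS:1-6|", "ATGGCC",
    ">|||", "ATG"), fa)
  expect_warning(ts <- readTranscriptReference(fa), "malformed")
  expect_identical(transcriptId(ts), "T1")
  expect_error(readTranscriptReference(tempfile()), "cannot read")
})

write_abundance <- function(ids, tpm) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(target_id = ids, tpm = tpm), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p
}

sample_sheet <- function(n) {
  data.frame(sample_id = paste0("s", seq_len(n)),
             stage = rep(c("GV", "MII"), length.out = n),
             age_group = "young",
             time_h = rep(c(0, 24), length.out = n))
}

test_that("abundance tables are assembled over the union of ids", {
  p1 <- write_abundance(c("T1", "T2"), c(5, 0))
  p2 <- write_abundance(c("T1", "T2"), c(5, 0))
  ab <- readAbundance(c(p1, p2), sample_sheet(2))
  expect_equal(dim(ab), c(2L, 2L))
  expect_equal(unname(SummarizedExperiment::assay(ab)["T1", ]), c(5, 5))

  p3 <- write_abundance("T1", 5)
  p4 <- write_abundance(c("T1", "T2"), c(5, 3))
  expect_warning(ab2 <- readAbundance(c(p3, p4), sample_sheet(2)), "filled")
  expect_equal(unname(SummarizedExperiment::assay(ab2)["T2", ]), c(0, 3))
})

test_that("duplicate ids are fatal; versioned ids stay distinct unless stripped", {
  dup <- write_abundance(c("T1", "T1"), c(1, 2))
  expect_error(readAbundance(dup, sample_sheet(1)), "duplicate")

  v1 <- write_abundance(c("ENST0A.1", "ENST0A.2"), c(1, 2))
  ab <- readAbundance(v1, sample_sheet(1))
  expect_setequal(rownames(ab), c("ENST0A.1", "ENST0A.2"))
  expect_error(readAbundance(v1, sample_sheet(1), stripVersion = TRUE),
               "duplicate")
  v2 <- write_abundance("ENST0B.7", 4)
  ab2 <- readAbundance(v2, sample_sheet(1), stripVersion = TRUE)
  expect_identical(rownames(ab2), "ENST0B")
})

test_that("the expression filter keeps >= minTpm in every sample, inclusively", {
  values <- rbind(a = c(0.5, 2, 2, 2), b = c(1, 1, 1, 1), c = c(5, 8, 2, 3))
  x <- make_experiment(values, c("GV", "GV", "MII", "MII"))
  kept <- filterExpressed(x, 1)
  expect_setequal(rownames(kept), c("b", "c"))     # boundary 1.0 retained
  expect_identical(rownames(filterExpressed(x, 0)), rownames(x))

  # idempotence and monotonicity in the threshold
  expect_identical(rownames(filterExpressed(kept, 1)), rownames(kept))
  for (thr in c(0.5, 1, 2, 4)) {
    hi <- rownames(suppressWarnings(filterExpressed(x, thr + 1)))
    lo <- rownames(suppressWarnings(filterExpressed(x, thr)))
    expect_true(all(hi %in% lo))
  }
  expect_warning(filterExpressed(x, 100), "no transcript")
})

test_that("protein tables average replicate iBAQ columns and keep group flags", {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(
    gene_id = c("G1", "G2"), n_protein_groups = c(1L, 2L),
    ibaq_gv_r1 = c(2, 10), ibaq_gv_r2 = c(4, 10),
    ibaq_mii_r1 = c(8, 0), ibaq_mii_r2 = c(10, 2)), p,
    sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readProteinTable(p)
  expect_equal(tab$ibaq_gv, c(3, 10))
  expect_equal(tab$ibaq_mii, c(9, 1))
  expect_equal(tab$n_protein_groups, c(1L, 2L))

  neg <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = "G1", n_protein_groups = 1L,
                                ibaq_gv = -1, ibaq_mii = 2), neg,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readProteinTable(neg), "negative iBAQ")

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene_id\tn_protein_groups\tibaq_gv\tibaq_mii", empty)
  expect_warning(tab0 <- readProteinTable(empty), "empty")
  expect_identical(nrow(tab0), 0L)
})

test_that("result tables round-trip through TSV at printed precision", {
  df <- data.frame(transcript_id = c("a", "b", "c"),
                   lambda = c(-0.0577623, NaN, -1 / 3),
                   half_life_h = c(12.000001, NA, 2.0794415))
  p <- tempfile(fileext = ".tsv")
  writeResultTable(df, p, comments = "unit test")
  raw <- readLines(p)
  expect_true(startsWith(raw[1], "# "))
  expect_true(any(grepl("\tNA\t", raw) | grepl("\tNA$", raw)))
  back <- readResultTable(p)
  expect_equal(back$half_life_h, df$half_life_h, tolerance = 1e-5)
  expect_equal(back$lambda[c(1, 3)], df$lambda[c(1, 3)], tolerance = 1e-5)

  p2 <- tempfile(fileext = ".tsv")
  writeResultTable(df[0, ], p2)
  expect_identical(length(readLines(p2)), 1L)    # header-only
})
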