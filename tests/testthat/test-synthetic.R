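small_cfg <- function(seed = 7L, ...) {
  simulationConfig(nTranscripts = 150L, seed = seed, cdsCodons = c(40L, 80L),
                   ...)
}

test_that("the generator is fully deterministic given (seed, config)", {
  cfg <- small_cfg()
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(as.character(cdsSeq(s1$transcripts)),
                   as.character(cdsSeq(s2$transcripts)))
  expect_identical(SummarizedExperiment::assay(s1$abundance),
                   SummarizedExperiment::assay(s2$abundance))
  expect_identical(s1$protein, s2$protein)

  other <- simulateStudy(small_cfg(seed = 8L))
  expect_false(identical(as.character(cdsSeq(s1$transcripts)),
                         as.character(cdsSeq(other$transcripts))))
})

test_that("simulated CDS are in-frame, start with ATG and end with a stop", {
  ts <- simulateTranscriptome(small_cfg())
  cds <- as.character(cdsSeq(ts))
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(startsWith(cds, "ATG")))
  expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                    c("TAA", "TAG", "TGA")))
})

test_that("an untilted transcriptome matches the uniform codon distribution", {
  cfg <- simulationConfig(nTranscripts = 60L, seed = 9L, gcTilt = 0,
                          cdsCodons = c(200L, 200L))
  ts <- simulateTranscriptome(cfg)
  freq <- codonFrequencies(cdsSeq(ts))
  # ATG is forced as the first codon; beyond that every sense codon is
  # uniform at 1/61. Pool all transcripts for a tight binomial check.
  total_codons <- 60 * 201
  pooled <- colMeans(freq)
  expect_true(all(abs(pooled[colnames(freq) != "ATG"] - 1 / 61) <
                    4 * sqrt((1 / 61) / total_codons)))
})

test_that("ground truth encodes multipliers and compositional factors exactly", {
  cfg <- small_cfg(agingCoupling = numeric(0), noiseCv = 0)
  ts <- simulateTranscriptome(cfg)
  truth <- assignTruth(cfg, ts)
  dec <- !truth$stable
  expect_equal(truth$half_life_aged[dec] / truth$half_life_young[dec],
               truth$multiplier[dec], tolerance = 1e-12)
  expect_true(all(truth$multiplier[dec & truth$category == "longer_in_aged"] > 1))
  d <- attr(truth, "degraded_fraction")
  expect_equal(unname(attr(truth, "implied_factor")), unname(1 / (1 - d)))

  # multipliers of 1 everywhere make every decaying transcript unchanged
  allsame <- assignTruth(small_cfg(
    agingCoupling = numeric(0),
    agingEffect = c(unchanged = 1, shorter_in_aged = 1, longer_in_aged = 1)), ts)
  expect_true(all(allsame$category[!allsame$stable] == "unchanged"))
})

test_that("a requested degraded mass fraction is realized exactly", {
  for (d in c(0.3, 0.6)) {
    cfg <- small_cfg(targetDegradedFraction = d)
    truth <- assignTruth(cfg, simulateTranscriptome(cfg))
    expect_equal(unname(attr(truth, "degraded_fraction")["young"]), d,
                 tolerance = 1e-9)
  }
  cfg_bad <- small_cfg(fracStable = 0, targetDegradedFraction = 0.5)
  expect_error(assignTruth(cfg_bad, simulateTranscriptome(cfg_bad)),
               "stable subset")
})

test_that("TPM columns sum to one million and composition cancels when stable", {
  cfg <- small_cfg(noiseCv = 0, fracStable = 1)
  study <- simulateStudy(cfg)
  a <- SummarizedExperiment::assay(study$abundance)
  expect_equal(unname(colSums(a)), rep(1e6, ncol(a)), tolerance = 1e-6)
  cd <- SummarizedExperiment::colData(study$abundance)
  gv <- a[, cd$stage == "GV"][, 1]
  mii <- a[, cd$stage == "MII"][, 1]
  expect_equal(mii, gv, tolerance = 1e-12)         # nothing decays
})

test_that("with half the mass degraded, stable TPM doubles (noise-free)", {
  cfg <- small_cfg(noiseCv = 0, fracStable = 0.3,
                   targetDegradedFraction = 0.5)
  study <- simulateStudy(cfg)
  a <- SummarizedExperiment::assay(study$abundance)
  cd <- SummarizedExperiment::colData(study$abundance)
  st <- study$truth$stable
  gv <- a[, which(cd$age_group == "young" & cd$stage == "GV")[1]]
  mii <- a[, which(cd$age_group == "young" & cd$stage == "MII")[1]]
  expect_equal(unname(mii[st] / gv[st]), rep(2, sum(st)), tolerance = 1e-9)
})

test_that("zero protein coupling leaves PACC centered on zero", {
  cfg <- simulationConfig(nTranscripts = 300L, seed = 10L,
                          cdsCodons = c(60L, 120L),
                          proteinCoupling = numeric(0),
                          halfLifeProteinCoupling = 0)
  study <- simulateStudy(cfg)
  freq <- codonFrequencies(cdsSeq(study$transcripts))
  rownames(freq) <- study$truth$gene_id
  keep <- study$protein$n_protein_groups == 1L
  delta <- with(study$protein[keep, ], setNames(ibaq_mii - ibaq_gv, gene_id))
  tab <- pacc(freq, delta)
  expect_lt(abs(median(tab$pacc, na.rm = TRUE)), 0.1)
  expect_gt(mean(study$protein$n_protein_groups == 1L), 0.85)
})

test_that("written study files are readable by the standard-format readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  study <- simulateStudy(cfg, dir = dir)
  # FASTA round trip recovers the region sequences
  ts2 <- readTranscriptReference(study$paths$fasta)
  expect_identical(as.character(cdsSeq(ts2)),
                   as.character(cdsSeq(study$transcripts)))
  expect_identical(as.character(utr5Seq(ts2)),
                   as.character(utr5Seq(study$transcripts)))
  # abundance round trip recovers the TPM matrix
  meta <- utils::read.delim(study$paths$metadata)
  ab2 <- readAbundance(meta$path,
                       meta[, c("sample_id", "stage", "age_group", "time_h")])
  a1 <- SummarizedExperiment::assay(study$abundance)
  a2 <- SummarizedExperiment::assay(ab2)[rownames(a1), ]
  expect_equal(a2, a1, tolerance = 1e-6, ignore_attr = TRUE)
  prot <- readProteinTable(study$paths$protein)
  expect_identical(nrow(prot), 150L)
})
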