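#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   trinucleotideFrequency letterFrequency subseq width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' TranscriptSet: CDS and UTR sequences for a set of transcripts
#'
#' Holds, for each transcript, its coding sequence and the two untranslated
#' regions as separate [Biostrings::DNAStringSet] objects, plus the gene each
#' transcript belongs to. Every CDS must be a nonempty multiple of 3
#' nucleotides over the A/C/G/T/N alphabet; UTRs may be empty.
#'
#' @slot cds DNAStringSet of coding sequences; names are transcript ids.
#' @slot utr5 DNAStringSet of 5' UTRs, parallel to `cds`.
#' @slot utr3 DNAStringSet of 3' UTRs, parallel to `cds`.
#' @slot geneId character vector of gene ids, parallel to `cds`.
#'
#' @seealso [readTranscriptReference()], [buildFeatureTable()]
#' @export
setClass("TranscriptSet",
  representation(
    cds = "DNAStringSet",
    utr5 = "DNAStringSet",
    utr3 = "DNAStringSet",
    geneId = "character"
  )
)

setValidity("TranscriptSet", function(object) {
  n <- length(object@cds)
  msg <- character()
  if (length(object@utr5) != n || length(object@utr3) != n ||
      length(object@geneId) != n)
    msg <- c(msg, "cds, utr5, utr3 and geneId must have equal length")
  ids <- names(object@cds)
  if (n > 0 && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    msg <- c(msg, "cds must carry unique, nonempty transcript ids as names")
  if (n > 0) {
    w <- Biostrings::width(object@cds)
    if (any(w == 0L) || any(w %% 3L != 0L))
      msg <- c(msg, "every CDS length must be a positive multiple of 3")
    ok <- Biostrings::letterFrequency(object@cds, "ACGTN")
    if (any(ok != w))
      msg <- c(msg, "CDS sequences may contain only A/C/G/T/N")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' @param transcriptId character vector of unique transcript ids.
#' @param geneId character vector of gene ids (recycled if length 1).
#' @param cds,utr5,utr3 character vectors or DNAStringSet; `utr5`/`utr3`
#'   default to empty sequences. RNA input is accepted: U is converted to T.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet("tx1", "gene1", cds = "ATGGCCTAA", utr5 = "GCAGCC")
#' cdsSeq(ts)
#' @export
TranscriptSet <- function(transcriptId, geneId, cds, utr5 = NULL, utr3 = NULL) {
  n <- length(transcriptId)
  if (length(geneId) == 1L) geneId <- rep(geneId, n)
  as_dna <- function(x, default_empty = FALSE) {
    if (is.null(x)) x <- rep("", n)
    if (is.character(x)) x <- chartr("Uu", "Tt", toupper(x))
    x <- Biostrings::DNAStringSet(x)
    names(x) <- transcriptId
    x
  }
  new("TranscriptSet",
    cds = as_dna(cds), utr5 = as_dna(utr5), utr3 = as_dna(utr3),
    geneId = as.character(geneId))
}

#' DecayExperiment: transcript abundance across oocyte maturation samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a transcripts x
#' samples abundance matrix (TPM on input; unitless after normalization).
#' The column metadata must describe each sample with `sample_id`, `stage`
#' (GV or MII), `age_group` (young or aged) and `time_h` (hours since the
#' GV reference point; 0 exactly for GV samples, positive for MII).
#'
#' @seealso [readAbundance()], [meanNormalize()], [fitAllDecay()]
#' @export
setClass("DecayExperiment", contains = "SummarizedExperiment")

setValidity("DecayExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "stage", "age_group", "time_h")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks required columns:", paste(miss, collapse = ", ")))
  if (!all(cd$stage %in% c("GV", "MII")))
    msg <- c(msg, "stage must be 'GV' or 'MII'")
  if (!all(cd$age_group %in% c("young", "aged")))
    msg <- c(msg, "age_group must be 'young' or 'aged'")
  if (!all((cd$time_h == 0) == (cd$stage == "GV")))
    msg <- c(msg, "time_h must be 0 exactly for GV samples and positive for MII")
  if (any(cd$time_h < 0)) msg <- c(msg, "time_h must be nonnegative")
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a)) msg <- c(msg, "abundance values must not be missing")
  else if (any(a < 0)) msg <- c(msg, "abundance values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a DecayExperiment
#'
#' @param values numeric matrix, transcripts x samples (TPM). Row names are
#'   transcript ids; column order must match `sampleData`.
#' @param sampleData data.frame with columns `sample_id`, `stage` (GV/MII),
#'   `age_group` (young/aged), `time_h` (0 for GV).
#' @param assayName name of the assay; `"tpm"` for raw input.
#' @return A [DecayExperiment-class] object.
#' @export
DecayExperiment <- function(values, sampleData, assayName = "tpm") {
  values <- as.matrix(values)
  sampleData <- as.data.frame(sampleData)
  if (ncol(values) != nrow(sampleData))
    stop("number of sample columns does not match sampleData rows")
  colnames(values) <- sampleData$sample_id
  assays <- list(values)
  names(assays) <- assayName
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id))
  new("DecayExperiment", se)
}

#' SimulationConfig: study conditions for the synthetic data generator
#'
#' Bundles every knob of the synthetic cohort. Defaults encode the study
#' conditions the analysis assumes: five replicates per stage and age group,
#' a 24 h GV-to-MII maturation window, lognormal replicate noise with
#' coefficient of variation 0.2, half-lives spread log-uniformly over
#' 4-20 h, and an age-dependent inversion of the GC-content/stability
#' coupling (GC-rich codon content shortens half-life among age-unaffected
#' transcripts and stabilizes the age-affected ones).
#'
#' Couplings are expressed per standard deviation of the named codon-class
#' fraction, on the log2 half-life scale (`codonCoupling`, applied to the
#' young half-life of age-unchanged transcripts), the log2 aging-multiplier
#' scale (`agingCoupling`, applied to age-changed transcripts), and the
#' protein-delta scale in units of its noise SD (`proteinCoupling`).
#'
#' @slot nTranscripts number of transcripts in the cohort.
#' @slot seed integer seed; the generator is fully deterministic given it.
#' @slot tMiiH hours between the GV (time zero) and MII timepoints.
#' @slot nReps replicates per (stage, age group) cell.
#' @slot noiseCv lognormal coefficient of variation of replicate noise.
#' @slot fracStable fraction of transcripts with zero decay rate.
#' @slot halfLifeRange baseline young half-life range in hours (log-uniform).
#' @slot codonCoupling named signed effects of codon-class z-scores on log2
#'   young half-life.
#' @slot agingCoupling named signed effects of codon-class z-scores on the
#'   log2 aged/young half-life multiplier of age-changed transcripts.
#' @slot agingEffect base half-life multipliers per category.
#' @slot proteinCoupling named signed effects of codon-class z-scores on the
#'   protein abundance delta.
#' @slot halfLifeProteinCoupling signed effect of (rank-transformed) young
#'   half-life on the protein delta.
#' @slot fracUnchanged fraction of decaying transcripts whose stability is
#'   not altered by aging.
#' @slot cdsCodons range of CDS lengths in codons (excluding start/stop).
#' @slot utrGc baseline UTR GC fraction.
#' @slot gcTilt half-width of the per-transcript GC tilt on codon sampling.
#' @slot truthNoiseSd SD of log2 half-life noise not explained by sequence.
#' @slot targetDegradedFraction optional target for the fraction of young
#'   mRNA mass degraded by MII; decay rates are rescaled to meet it exactly
#'   (NA disables).
#' @slot c0Meanlog,c0Sdlog lognormal parameters of initial abundance.
#' @slot fracMultiProtein fraction of genes flagged with >1 protein group.
#' @export
setClass("SimulationConfig",
  representation(
    nTranscripts = "integer", seed = "integer", tMiiH = "numeric",
    nReps = "integer", noiseCv = "numeric", fracStable = "numeric",
    halfLifeRange = "numeric", codonCoupling = "numeric",
    agingCoupling = "numeric", agingEffect = "numeric",
    proteinCoupling = "numeric", halfLifeProteinCoupling = "numeric",
    fracUnchanged = "numeric", cdsCodons = "integer", utrGc = "numeric",
    gcTilt = "numeric", truthNoiseSd = "numeric",
    targetDegradedFraction = "numeric", c0Meanlog = "numeric",
    c0Sdlog = "numeric", fracMultiProtein = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be positive")
  if (object@nReps < 3L) msg <- c(msg, "nReps must be at least 3")
  if (object@tMiiH <= 0) msg <- c(msg, "tMiiH must be positive")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be nonnegative")
  if (!frac_ok(object@fracStable)) msg <- c(msg, "fracStable must be in [0,1]")
  if (!frac_ok(object@fracUnchanged))
    msg <- c(msg, "fracUnchanged must be in [0,1]")
  if (!frac_ok(object@fracMultiProtein))
    msg <- c(msg, "fracMultiProtein must be in [0,1]")
  if (length(object@halfLifeRange) != 2L || object@halfLifeRange[1] <= 0 ||
      diff(object@halfLifeRange) < 0)
    msg <- c(msg, "halfLifeRange must be (low, high) with low > 0")
  if (!is.na(object@targetDegradedFraction) &&
      (object@targetDegradedFraction <= 0 || object@targetDegradedFraction >= 1))
    msg <- c(msg, "targetDegradedFraction must be in (0,1) or NA")
  cls <- c("nnS", "nSS", "SSn", "SSS", "nnW", "nWW", "WWn", "WWW")
  for (s in c("codonCoupling", "agingCoupling", "proteinCoupling")) {
    v <- slot(object, s)
    if (length(v) && !all(names(v) %in% cls))
      msg <- c(msg, paste0(s, " names must be codon classes (",
                           paste(cls, collapse = "/"), ")"))
  }
  if (!all(c("unchanged", "shorter_in_aged", "longer_in_aged") %in%
           names(object@agingEffect)))
    msg <- c(msg, "agingEffect must name unchanged/shorter_in_aged/longer_in_aged")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning and defaults of every
#' parameter.
#'
#' @param nTranscripts,seed,tMiiH,nReps,noiseCv,fracStable,halfLifeRange
#'   cohort-level settings; see class documentation.
#' @param codonCoupling,agingCoupling,agingEffect,proteinCoupling,
#'   halfLifeProteinCoupling,fracUnchanged effect structure of the truth.
#' @param cdsCodons,utrGc,gcTilt,truthNoiseSd,targetDegradedFraction,
#'   c0Meanlog,c0Sdlog,fracMultiProtein sequence and abundance settings.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nTranscripts = 200, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nTranscripts = 2000L, seed = 1L, tMiiH = 24,
    nReps = 5L, noiseCv = 0.2, fracStable = 0.1, halfLifeRange = c(4, 20),
    codonCoupling = c(SSS = -0.6),
    agingCoupling = c(SSS = 0.8),
    agingEffect = c(unchanged = 1, shorter_in_aged = 0.7,
                    longer_in_aged = 1.3),
    proteinCoupling = c(SSS = 1),
    halfLifeProteinCoupling = -0.5,
    fracUnchanged = 0.5, cdsCodons = c(100L, 300L), utrGc = 0.45,
    gcTilt = 1.2, truthNoiseSd = 0.15, targetDegradedFraction = NA_real_,
    c0Meanlog = 3, c0Sdlog = 1.2, fracMultiProtein = 0.05) {
  new("SimulationConfig",
    nTranscripts = as.integer(nTranscripts), seed = as.integer(seed),
    tMiiH = tMiiH, nReps = as.integer(nReps), noiseCv = noiseCv,
    fracStable = fracStable, halfLifeRange = as.numeric(halfLifeRange),
    codonCoupling = codonCoupling, agingCoupling = agingCoupling,
    agingEffect = agingEffect, proteinCoupling = proteinCoupling,
    halfLifeProteinCoupling = halfLifeProteinCoupling,
    fracUnchanged = fracUnchanged, cdsCodons = as.integer(cdsCodons),
    utrGc = utrGc, gcTilt = gcTilt, truthNoiseSd = truthNoiseSd,
    targetDegradedFraction = targetDegradedFraction, c0Meanlog = c0Meanlog,
    c0Sdlog = c0Sdlog, fracMultiProtein = fracMultiProtein)
}

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object@cds), "transcripts\n")
  if (length(object@cds)) {
    w <- Biostrings::width(object@cds)
    cat("  CDS length: median", stats::median(w), "nt (range",
        min(w), "-", max(w), ")\n")
    cat("  first ids:", paste(utils::head(names(object@cds), 3),
                              collapse = ", "), "\n")
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTranscripts, "transcripts, seed",
      object@seed, "\n")
  cat("  t(MII) =", object@tMiiH, "h;", object@nReps,
      "reps/stage; noise CV", object@noiseCv, "\n")
  cat("  half-life range", paste(object@halfLifeRange, collapse = "-"),
      "h; stable fraction", object@fracStable, "\n")
})
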