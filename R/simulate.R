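# Ground-truth-known synthetic data with the statistical structure the
# analysis assumes: transcriptional quiescence (decay only), exponential
# per-transcript decay, compositional TPM renormalization, lognormal
# replicate noise, and controllable couplings of codon-class content to
# half-life, aging response and protein output.
#
# Each generator stage seeds the RNG from the configuration (seed, seed+1,
# seed+2, seed+3), so a cohort is fully reproducible given (seed, config).

# z-scored codon-class fraction matrix for the configured coupling names.
.class_z <- function(cds, classes) {
  if (!length(classes)) return(NULL)
  cf <- codonClassFractions(cds)[, classes, drop = FALSE]
  scale(cf)
}

.coupling_term <- function(cds, coupling) {
  if (!length(coupling)) return(0)
  z <- .class_z(cds, names(coupling))
  as.vector(z %*% coupling)
}

#' Simulate a transcriptome with controlled codon composition
#'
#' Samples each CDS codon-by-codon from the 61 sense codons under a
#' per-transcript GC tilt (log-linear in the codon's G+C count), so codon-
#' class content varies smoothly across transcripts; prepends ATG and
#' appends a stop codon. UTR sequences are sampled with a GC fraction tied
#' to the same tilt axis. Deterministic given `cfg@seed`.
#'
#' @param cfg A [SimulationConfig-class].
#' @return A [TranscriptSet-class] with ids `TX...` and genes `GENE...`.
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed)
  n <- cfg@nTranscripts
  ids <- sprintf("TX%05d", seq_len(n))
  genes <- sprintf("GENE%05d", seq_len(n))
  gc_count <- vapply(strsplit(.SENSE_CODONS, ""),
                     function(b) sum(b %in% c("G", "C")), numeric(1))
  s_c <- gc_count - mean(gc_count)
  tilt <- stats::runif(n, -cfg@gcTilt, cfg@gcTilt)
  len_grid <- seq(cfg@cdsCodons[1], cfg@cdsCodons[2])
  n_codons <- len_grid[sample.int(length(len_grid), n, replace = TRUE)]
  cds <- vapply(seq_len(n), function(i) {
    p <- exp(tilt[i] * s_c)
    body <- sample(.SENSE_CODONS, n_codons[i], replace = TRUE, prob = p)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  utr_gc <- stats::plogis(stats::qlogis(cfg@utrGc) + 0.6 * tilt)
  sample_utr <- function(len, gc) {
    if (len == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  u5_len <- sample(5:150, n, replace = TRUE)
  u3_len <- sample(30:300, n, replace = TRUE)
  utr5 <- vapply(seq_len(n), function(i) sample_utr(u5_len[i], utr_gc[i]),
                 character(1))
  utr3 <- vapply(seq_len(n), function(i) sample_utr(u3_len[i], utr_gc[i]),
                 character(1))
  TranscriptSet(ids, genes, cds, utr5, utr3)
}

#' Assign ground-truth decay parameters to a simulated transcriptome
#'
#' Draws the young half-life log-uniformly over `cfg@halfLifeRange`, adds
#' the configured codon-class couplings (log2 scale, per SD of class
#' fraction) and lognormal truth noise; marks a `fracStable` subset as
#' stable (zero decay rate). Aged half-lives are the young ones times a
#' category multiplier: the base multipliers come from `cfg@agingEffect`
#' and, for age-changed transcripts, `cfg@agingCoupling` tilts the
#' multiplier with codon-class content. The true change category is then
#' recomputed from the realized half-lives with the 1-h rule, so truth and
#' classification share semantics. When `cfg@targetDegradedFraction` is
#' set, the stable transcripts' initial abundance is reweighted so the
#' young group's degraded mRNA mass fraction at `tMiiH` equals the target
#' exactly, without touching any half-life.
#'
#' @param cfg A [SimulationConfig-class].
#' @param ts The [TranscriptSet-class] from [simulateTranscriptome()].
#' @return data.frame with per-transcript truth (`half_life_young/aged`,
#'   `lambda_young/aged` as signed slopes, `multiplier`, `stable`,
#'   `category`, initial abundance `c0`), plus attributes
#'   `degraded_fraction` and `implied_factor` (named per age group: the
#'   compositional decay factor `1/(1-d)`).
#' @export
assignTruth <- function(cfg, ts) {
  stopifnot(is(cfg, "SimulationConfig"), is(ts, "TranscriptSet"))
  set.seed(cfg@seed + 1L)
  n <- length(ts)
  lo <- cfg@halfLifeRange[1]
  hi <- cfg@halfLifeRange[2]
  base <- stats::runif(n, log2(lo), log2(hi))
  couple <- .coupling_term(cdsSeq(ts), cfg@codonCoupling)
  hl_young <- 2^(base + couple + stats::rnorm(n, 0, cfg@truthNoiseSd))
  stable <- stats::runif(n) < cfg@fracStable

  unchanged <- stats::runif(n) < cfg@fracUnchanged
  direction <- sample(c("shorter_in_aged", "longer_in_aged"), n,
                      replace = TRUE)
  base_mult <- ifelse(unchanged, cfg@agingEffect[["unchanged"]],
                      cfg@agingEffect[direction])
  mult <- base_mult
  if (length(cfg@agingCoupling)) {
    tiltm <- .coupling_term(cdsSeq(ts), cfg@agingCoupling)
    mult[!unchanged] <- base_mult[!unchanged] * 2^(tiltm[!unchanged])
  }
  hl_aged <- hl_young * mult

  c0 <- stats::rlnorm(n, cfg@c0Meanlog, cfg@c0Sdlog)
  lam <- function(hl) ifelse(stable, 0, -log(2) / hl)
  lam_young <- lam(hl_young)
  lam_aged <- lam(hl_aged)

  hl_young <- ifelse(stable, Inf, hl_young)
  hl_aged <- ifelse(stable, Inf, hl_aged)

  if (!is.na(cfg@targetDegradedFraction)) {
    # Reweight the stable transcripts' initial abundance so the young
    # group's degraded mass fraction at tMiiH equals the target, leaving
    # individual half-lives (and hence the stable/decaying fold-change
    # separation) untouched.
    target <- cfg@targetDegradedFraction
    if (!any(stable))
      stop("targetDegradedFraction requires a stable subset")
    S <- sum(c0[stable])
    B <- sum(c0[!stable])
    A <- sum(c0[!stable] * exp(lam_young[!stable] * cfg@tMiiH))
    w <- ((1 - target) * B - A) / (S * target)
    if (!is.finite(w) || w <= 0)
      stop("targetDegradedFraction unreachable: decaying transcripts retain ",
           signif(A / B, 3), " of their mass, so the target must be below ",
           signif(1 - A / B, 3))
    c0[stable] <- c0[stable] * w
  }

  d_change <- hl_aged - hl_young
  category <- rep(NA_character_, n)
  dec <- !stable
  category[dec & abs(d_change) < 1] <- "unchanged"
  category[dec & d_change <= -1] <- "shorter_in_aged"
  category[dec & d_change >= 1] <- "longer_in_aged"

  degraded <- vapply(list(young = lam_young, aged = lam_aged), function(l)
    1 - sum(c0 * exp(l * cfg@tMiiH)) / sum(c0), numeric(1))
  out <- data.frame(
    transcript_id = transcriptId(ts), gene_id = geneId(ts),
    stable = stable, half_life_young = hl_young, half_life_aged = hl_aged,
    lambda_young = lam_young, lambda_aged = lam_aged,
    multiplier = ifelse(stable, NA_real_, mult),
    category = category, c0 = c0, row.names = NULL)
  attr(out, "degraded_fraction") <- degraded
  attr(out, "implied_factor") <- 1 / (1 - degraded)
  out
}

#' Simulate the TPM abundance matrix from truth
#'
#' Expected GV abundance is the transcript's initial abundance `c0` and
#' expected MII abundance is `c0 * exp(lambda * tMiiH)`; every sample gets
#' mean-preserving multiplicative lognormal noise with coefficient of
#' variation `cfg@noiseCv`, and every sample column is rescaled to sum to
#' 10^6 (TPM). The rescaling induces the compositional distortion that
#' decay-factor normalization must undo: with most mass degraded by MII,
#' stable transcripts' TPM rises.
#'
#' @param cfg A [SimulationConfig-class].
#' @param truth data.frame from [assignTruth()].
#' @return A [DecayExperiment-class] with `2 * 2 * cfg@nReps` samples
#'   (young/aged x GV/MII x replicates).
#' @export
simulateAbundance <- function(cfg, truth) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed + 2L)
  n <- nrow(truth)
  sigma <- sqrt(log(1 + cfg@noiseCv^2))
  cols <- list()
  meta <- list()
  for (ag in .age_groups) {
    lam <- truth[[paste0("lambda_", ag)]]
    for (st in .stages) {
      t_h <- if (st == "GV") 0 else cfg@tMiiH
      mu <- truth$c0 * exp(lam * t_h)
      for (r in seq_len(cfg@nReps)) {
        noise <- if (sigma > 0)
          exp(stats::rnorm(n, -sigma^2 / 2, sigma)) else rep(1, n)
        v <- mu * noise
        cols[[length(cols) + 1L]] <- v / sum(v) * 1e6
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = paste(ag, st, r, sep = "_"), stage = st,
          age_group = ag, time_h = t_h)
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- truth$transcript_id
  DecayExperiment(values, do.call(rbind, meta))
}

#' Simulate protein abundance (iBAQ) deltas from truth
#'
#' The GV-to-MII protein change of each gene is a weighted sum of its
#' codon-class content (`cfg@proteinCoupling`), a monotone transform of
#' the true young half-life (`cfg@halfLifeProteinCoupling`, applied to the
#' rank-standardized half-life so stable transcripts are handled) and
#' unit-SD noise, scaled to iBAQ units. A `fracMultiProtein` subset is
#' flagged with more than one protein group to exercise the
#' single-protein-group filter.
#'
#' @param cfg A [SimulationConfig-class].
#' @param truth data.frame from [assignTruth()].
#' @param ts matching [TranscriptSet-class].
#' @return data.frame with `gene_id`, `n_protein_groups`, `ibaq_gv`,
#'   `ibaq_mii`.
#' @export
simulateProtein <- function(cfg, truth, ts) {
  stopifnot(is(cfg, "SimulationConfig"), is(ts, "TranscriptSet"))
  set.seed(cfg@seed + 3L)
  n <- nrow(truth)
  s <- .coupling_term(cdsSeq(ts), cfg@proteinCoupling)
  zh <- as.vector(scale(rank(truth$half_life_young)))
  s <- s + cfg@halfLifeProteinCoupling * zh + stats::rnorm(n)
  delta <- s * 1e5
  gv <- stats::rlnorm(n, log(1e6), 0.5)
  multi <- stats::runif(n) < cfg@fracMultiProtein
  data.frame(
    gene_id = truth$gene_id,
    n_protein_groups = ifelse(multi,
                              sample(2:4, n, replace = TRUE), 1L),
    ibaq_gv = gv,
    ibaq_mii = pmax(gv + delta, 0),
    row.names = NULL)
}

# GENCODE-style header for a simulated transcript.
.sim_header <- function(id, gene, u5, cds, u3) {
  parts <- c(id, gene)
  pos <- 1L
  if (u5 > 0L) {
    parts <- c(parts, sprintf("UTR5:%d-%d", pos, pos + u5 - 1L))
    pos <- pos + u5
  }
  parts <- c(parts, sprintf("CDS:%d-%d", pos, pos + cds - 1L))
  pos <- pos + cds
  if (u3 > 0L)
    parts <- c(parts, sprintf("UTR3:%d-%d", pos, pos + u3 - 1L))
  paste0(paste(parts, collapse = "|"), "|")
}

#' Generate a full synthetic study, optionally on disk
#'
#' Runs [simulateTranscriptome()], [assignTruth()], [simulateAbundance()]
#' and [simulateProtein()] under one configuration. With `dir` set, writes
#' every input in the pipeline's external formats: `ref.fa` (GENCODE-style
#' headers), one kallisto-style abundance TSV per sample under
#' `abundance/`, `metadata.tsv`, `protein.tsv` and `truth.tsv`, so
#' integration tests exercise the real readers.
#'
#' @param cfg A [SimulationConfig-class].
#' @param dir output directory (created); `NULL` keeps everything in
#'   memory.
#' @return list with `transcripts`, `truth`, `abundance`, `protein` and,
#'   when written, `paths` (named file paths, with `abundance` a vector
#'   and `metadata` the sample sheet).
#' @export
simulateStudy <- function(cfg, dir = NULL) {
  ts <- simulateTranscriptome(cfg)
  truth <- assignTruth(cfg, ts)
  ab <- simulateAbundance(cfg, truth)
  prot <- simulateProtein(cfg, truth, ts)
  out <- list(transcripts = ts, truth = truth, abundance = ab,
              protein = prot)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "abundance"), recursive = TRUE,
               showWarnings = FALSE)
    u5 <- Biostrings::width(utr5Seq(ts))
    cw <- Biostrings::width(cdsSeq(ts))
    u3 <- Biostrings::width(utr3Seq(ts))
    full <- Biostrings::xscat(utr5Seq(ts), cdsSeq(ts), utr3Seq(ts))
    names(full) <- vapply(seq_along(ts), function(i)
      .sim_header(transcriptId(ts)[i], geneId(ts)[i], u5[i], cw[i], u3[i]),
      character(1))
    fa <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(full, fa)
    cd <- as.data.frame(SummarizedExperiment::colData(ab))
    a <- SummarizedExperiment::assay(ab)
    ab_paths <- vapply(seq_len(nrow(cd)), function(j) {
      p <- file.path(dir, "abundance", paste0(cd$sample_id[j], ".tsv"))
      utils::write.table(
        data.frame(target_id = rownames(a), length = u5 + cw + u3,
                   eff_length = u5 + cw + u3, est_counts = a[, j],
                   tpm = a[, j]),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }, character(1))
    meta_path <- file.path(dir, "metadata.tsv")
    utils::write.table(cbind(cd, path = ab_paths), meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prot_path <- file.path(dir, "protein.tsv")
    utils::write.table(prot, prot_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- list(fasta = fa, abundance = ab_paths,
                      metadata = meta_path, protein = prot_path,
                      truth = truth_path)
  }
  out
}
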