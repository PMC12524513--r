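# End-to-end orchestration: ingest -> normalize -> fit (young, aged) ->
# compare -> classify -> features -> profiles -> CSC/PACC -> RNA-protein,
# with structured per-stage logging and a JSON manifest.

#' Build a pipeline configuration
#'
#' All statistical defaults are the analysis' reference values: expression
#' floor of 1 TPM in every sample, 24 h GV-to-MII window, decay-fit alpha
#' 0.05, 1-h change threshold, CSC filter band (-0.1, 0.1), decay-factor
#' threshold grid starting at 1.0 in steps of 0.5.
#'
#' @param referenceFasta transcript reference FASTA path.
#' @param metadata sample sheet path (TSV with `sample_id`, `stage`,
#'   `age_group`, `time_h`, `path` pointing at per-sample abundance TSVs).
#' @param proteinTable optional protein iBAQ TSV path; `NULL` skips the
#'   protein stages.
#' @param outDir output directory for result tables and the manifest.
#' @param minTpm,tMiiH,alpha,deltaH,cscFilterBand,minBinSize statistical
#'   parameters (see module functions).
#' @param thresholdStart,thresholdStep,maxThreshold decay-factor threshold
#'   grid.
#' @param requireSignificance,zDenominator,stripVersion policies passed to
#'   [classifyChange()], [compareAges()] and [readAbundance()].
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(referenceFasta, metadata, proteinTable = NULL,
    outDir = "results", minTpm = 1.0, tMiiH = 24, alpha = 0.05,
    deltaH = 1.0, cscFilterBand = c(-0.1, 0.1), minBinSize = 20L,
    thresholdStart = 1.0, thresholdStep = 0.5, maxThreshold = 10.0,
    requireSignificance = TRUE, zDenominator = "sum",
    stripVersion = FALSE) {
  cfg <- list(referenceFasta = referenceFasta, metadata = metadata,
              proteinTable = proteinTable, outDir = outDir, minTpm = minTpm,
              tMiiH = tMiiH, alpha = alpha, deltaH = deltaH,
              cscFilterBand = cscFilterBand, minBinSize = minBinSize,
              thresholdStart = thresholdStart, thresholdStep = thresholdStep,
              maxThreshold = maxThreshold,
              requireSignificance = requireSignificance,
              zDenominator = zDenominator, stripVersion = stripVersion)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' Returns a character vector of human-readable problems (empty when the
#' configuration is usable); never mutates its input. Unknown keys are
#' reported as warnings-level problems.
#'
#' @param cfg A `PipelineConfig` (or plain list).
#' @return character vector of problems.
#' @export
validatePipelineConfig <- function(cfg) {
  problems <- character()
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    problems <- c(problems,
                  paste("warning: unknown key(s):", paste(extra, collapse = ", ")))
  need <- c("referenceFasta", "metadata", "outDir")
  for (k in need)
    if (is.null(cfg[[k]]) || !nzchar(cfg[[k]]))
      problems <- c(problems, paste("missing required path:", k))
  num_pos <- c(tMiiH = cfg$tMiiH, alpha = cfg$alpha, deltaH = cfg$deltaH,
               thresholdStep = cfg$thresholdStep)
  for (k in names(num_pos))
    if (!is.numeric(num_pos[[k]]) || num_pos[[k]] <= 0)
      problems <- c(problems, paste(k, "must be positive"))
  if (is.numeric(cfg$minTpm) && cfg$minTpm < 0)
    problems <- c(problems, "minTpm must be nonnegative")
  if (is.numeric(cfg$alpha) && cfg$alpha > 1)
    problems <- c(problems, "alpha must be at most 1")
  if (!is.null(cfg$cscFilterBand) &&
      (length(cfg$cscFilterBand) != 2L ||
       cfg$cscFilterBand[1] > cfg$cscFilterBand[2]))
    problems <- c(problems, "cscFilterBand must be (low, high) with low <= high")
  problems
}

.log_stage <- function(log, stage, ...) {
  msg <- paste0("[", stage, "] ", ...)
  message(msg)
  c(log, msg)
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs and writes all result
#' tables plus `manifest.json` (configuration hash, per-stage record
#' counts, file list) into `outDir`. Any stage failure aborts with the
#' stage name. When the protein table is absent the RNA-only stages still
#' run and the protein stages are skipped with a warning.
#'
#' @param cfg A `PipelineConfig` from [pipelineConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(cfg) {
  problems <- validatePipelineConfig(cfg)
  hard <- problems[!startsWith(problems, "warning:")]
  if (length(hard))
    stop("invalid configuration: ", paste(hard, collapse = "; "))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  # the hash identifies the analysis (inputs and parameters), not where its
  # results happen to be written
  hash <- .config_hash(unclass(cfg)[setdiff(names(cfg), "outDir")])
  prov <- c(paste("oocyteDecay", as.character(utils::packageVersion("oocyteDecay"))),
            paste("config", hash))
  log <- character()
  files <- character()
  counts <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(name, df) {
    p <- file.path(cfg$outDir, paste0(name, ".tsv"))
    writeResultTable(df, p, comments = prov)
    files[[name]] <<- p
  }

  ts <- run_stage("ingest_reference",
                  readTranscriptReference(cfg$referenceFasta))
  counts$reference <- length(ts)
  log <- .log_stage(log, "ingest_reference", length(ts), " transcripts")

  meta <- utils::read.delim(cfg$metadata, stringsAsFactors = FALSE)
  ab <- run_stage("ingest_abundance",
                  readAbundance(meta$path, meta[, c("sample_id", "stage",
                                                    "age_group", "time_h")],
                                stripVersion = cfg$stripVersion))
  counts$abundance_transcripts <- nrow(ab)
  counts$samples <- ncol(ab)
  log <- .log_stage(log, "ingest_abundance", nrow(ab), " transcripts x ",
                    ncol(ab), " samples")

  fits <- list()
  factors <- list()
  for (ag in intersect(.age_groups,
                       SummarizedExperiment::colData(ab)$age_group)) {
    sub <- ab[, SummarizedExperiment::colData(ab)$age_group == ag]
    sub <- run_stage(paste0("filter_", ag), filterExpressed(sub, cfg$minTpm))
    counts[[paste0("expressed_", ag)]] <- nrow(sub)
    nm <- run_stage(paste0("normalize_", ag), meanNormalize(sub))
    sel <- run_stage(paste0("decay_factor_", ag),
                     selectDecayThreshold(nm, cfg$thresholdStart,
                                          cfg$thresholdStep,
                                          cfg$maxThreshold))
    factors[[ag]] <- sel
    nm <- applyDecayFactor(nm, sel$result$factor)
    fit <- run_stage(paste0("fit_", ag), fitAllDecay(nm, cfg$alpha))
    fits[[ag]] <- fit
    counts[[paste0("decay_fit_", ag)]] <- sum(fit$decay_fit)
    log <- .log_stage(log, paste0("fit_", ag), nrow(fit), " transcripts, ",
                      sum(fit$decay_fit), " in decay-fit set; factor ",
                      signif(sel$result$factor, 4), " at threshold ",
                      sel$threshold)
    emit(paste0("fits_", ag), fit)
  }

  comp <- run_stage("compare_ages",
                    compareAges(fits$young, fits$aged,
                                zDenominator = cfg$zDenominator))
  comp <- run_stage("classify",
                    classifyChange(comp, cfg$deltaH, cfg$requireSignificance))
  counts$shared <- nrow(comp)
  counts$significant <- sum(comp$significant, na.rm = TRUE)
  counts$by_category <- as.list(table(comp$category))
  log <- .log_stage(log, "compare_ages", nrow(comp), " shared transcripts, ",
                    counts$significant, " significant")
  emit("comparison", comp)
  emit("category_summary", summarizeHalfLives(comp))

  features <- run_stage("features", buildFeatureTable(ts))
  counts$features <- nrow(features)
  emit("features", features)
  freq <- codonFrequencies(cdsSeq(ts))

  profiles <- list()
  for (arm in c("unaffected", "affected")) {
    bins <- binByYoungHalfLife(comp, arm)
    counts[[paste0("binned_", arm)]] <- nrow(bins)
    prof <- run_stage(paste0("profile_", arm),
                      featureHalfLifeCorrelations(bins, features,
                                                  cfg$minBinSize))
    prof$arm <- arm
    profiles[[arm]] <- prof
    per_bin <- run_stage(paste0("csc_", arm),
                         cscPerBin(bins, freq, cfg$minBinSize))
    csc <- aggregateCsc(per_bin, cfg$cscFilterBand)
    csc$arm <- arm
    emit(paste0("csc_", arm), csc)
    assign(paste0("csc_", arm), csc)
  }
  emit("feature_profiles", do.call(rbind, profiles))
  prof_cor <- run_stage("profile_correlation",
                        correlationOfProfiles(profiles$unaffected,
                                              profiles$affected))
  counts$profile_correlation <- prof_cor
  log <- .log_stage(log, "profile_correlation", "rho ",
                    signif(prof_cor$rho, 3), " over ", prof_cor$n,
                    " features")

  rna_protein <- data.frame(quantity = "profile_correlation_rho",
                            value = prof_cor$rho, n = prof_cor$n)
  if (!is.null(cfg$proteinTable) && file.exists(cfg$proteinTable)) {
    prot <- run_stage("ingest_protein", readProteinTable(cfg$proteinTable))
    counts$protein_genes <- nrow(prot)
    counts$protein_single_group <- sum(prot$n_protein_groups == 1L)
    geneMap <- data.frame(transcript_id = transcriptId(ts),
                          gene_id = geneId(ts))
    gene_freq <- freq
    rownames(gene_freq) <- geneMap$gene_id[
      match(rownames(freq), geneMap$transcript_id)]
    pacc_tab <- run_stage("pacc",
                          pacc(gene_freq, .protein_deltas(prot)))
    emit("pacc", pacc_tab)
    hl_cor <- run_stage("protein_half_life",
                        proteinHalfLifeCorrelation(fits$young, prot, geneMap))
    pf <- run_stage("protein_features",
                    proteinFeatureCorrelations(features, prot, comp, geneMap))
    emit("protein_feature_correlations", pf)
    for (arm in c("unaffected", "affected")) {
      cp <- run_stage(paste0("csc_vs_pacc_", arm),
                      cscVsPacc(get(paste0("csc_", arm)), pacc_tab))
      rna_protein <- rbind(rna_protein,
                           data.frame(quantity = paste0("csc_pacc_rho_", arm),
                                      value = cp$rho, n = cp$n))
    }
    rna_protein <- rbind(rna_protein,
                         data.frame(quantity = "half_life_protein_rho",
                                    value = hl_cor$rho, n = hl_cor$n))
  } else {
    warning("no protein table configured; protein stages skipped")
    log <- .log_stage(log, "protein", "skipped (no table)")
  }
  emit("rna_protein", rna_protein)

  manifest <- list(package = "oocyteDecay",
                   version = as.character(utils::packageVersion("oocyteDecay")),
                   config_hash = hash,
                   config = unclass(cfg),
                   counts = counts,
                   decay_factors = lapply(factors, function(s)
                     list(threshold = s$threshold,
                          factor = s$result$factor,
                          n_stable = s$result$n_stable)),
                   files = as.list(files),
                   log = log)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
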