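# Shared fixture builders. Everything is generated in code; no data files.

# A DecayExperiment from a plain matrix and parallel sample descriptors.
make_experiment <- function(values, stage, age_group = "young",
                            t_mii = 24, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids))
    ids <- if (!is.null(rownames(values))) rownames(values)
           else paste0("tx", seq_len(nrow(values)))
  rownames(values) <- ids
  n <- ncol(values)
  if (length(age_group) == 1L) age_group <- rep(age_group, n)
  sd <- data.frame(
    sample_id = paste(age_group, stage, seq_len(n), sep = "_"),
    stage = stage, age_group = age_group,
    time_h = ifelse(stage == "GV", 0, t_mii))
  DecayExperiment(values, sd)
}

# A minimal fits data.frame in the shape fitAllDecay() produces.
make_fits <- function(ids, lambda, se, age_group = "young") {
  data.frame(
    transcript_id = ids, age_group = age_group, lambda = lambda,
    se_lambda = se, sigma2 = se^2, t_stat = lambda / se,
    p_value = 2 * stats::pnorm(-abs(lambda / se)),
    half_life_h = ifelse(lambda < 0, log(0.5) / lambda, NA_real_),
    n_obs = 10L, n_floored = 0L, decay_fit = lambda < 0)
}

# A classified comparison table built directly from half-life pairs.
make_comparisons <- function(hy, ha, significant = TRUE, ids = NULL) {
  if (is.null(ids)) ids <- paste0("tx", seq_along(hy))
  comp <- data.frame(
    transcript_id = ids,
    lambda_young = log(0.5) / hy, se_lambda_young = 0.01,
    half_life_h_young = hy,
    lambda_aged = log(0.5) / ha, se_lambda_aged = 0.01,
    half_life_h_aged = ha,
    z = 0, p_value = 1, p_bonf = 1,
    significant = rep(significant, length.out = length(hy)))
  classifyChange(comp, requireSignificance = FALSE)
}

# Run the decay stage of the pipeline on one age group of a simulated study.
fit_age_group <- function(ab, ag, alpha = 0.05) {
  cd <- SummarizedExperiment::colData(ab)
  nm <- meanNormalize(filterExpressed(ab[, cd$age_group == ag]))
  sel <- suppressWarnings(selectDecayThreshold(nm))
  fitAllDecay(applyDecayFactor(nm, sel$result$factor), alpha = alpha)
}

# Classified young/aged comparison for a whole simulated study.
compare_study <- function(study, requireSignificance = FALSE) {
  comp <- compareAges(fit_age_group(study$abundance, "young"),
                      fit_age_group(study$abundance, "aged"))
  classifyChange(comp, requireSignificance = requireSignificance)
}

# Codon helpers used by several files.
codons_of_class <- function(class) {
  m <- codonClassMatrix()
  setdiff(rownames(m)[m[, class]], c("TAA", "TAG", "TGA"))
}

# Number of strong (G/C) bases per codon, for AU/GC-majority calls.
strong_count <- function(codons) {
  vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")),
         numeric(1))
}
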