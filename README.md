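# oocyteDecay

Estimation and comparison of maternal mRNA half-lives across the human
oocyte GV-to-MII transition, with codon-optimality statistics, for
transcriptomics researchers studying translation-coupled mRNA decay and
reproductive aging.

## The problem and the model

Fully grown GV-stage oocytes are transcriptionally quiescent: between the
germinal-vesicle (GV) and metaphase-II (MII) stages, transcript abundance
can only fall. Because TPM is compositional (every library sums to 10^6),
global decay inflates the apparent abundance of stable transcripts — if a
fraction *d* of the mRNA mass is lost, a stable transcript appears to rise
1/(1−d)-fold. The pipeline therefore:

1. filters to transcripts with ≥ 1 TPM in every sample of an age group;
2. normalizes each transcript to its GV (time-zero) mean;
3. estimates the **decay factor** 1/(1−d) from apparently stable
   transcripts (mean MII fold change above an iteratively selected
   threshold, replicate variance below the fold change) and divides the
   MII samples by it;
4. fits the linearized exponential decay model per transcript,

       C_t = C_0 · e^(−λt),   λ̂ = Σ(xᵢ−x̄)(yᵢ−ȳ) / Σ(xᵢ−x̄)²,
       σ² = Σ(yᵢ−ŷᵢ)²/(n−2),  SE_λ = √(σ²/Σ(xᵢ−x̄)²),
       t_λ = λ̂/SE_λ,          t½ = ln(0.5)/λ̂   (λ̂ < 0),

   calling the *decay-fit set* as λ̂ < 0 with two-sided p < 0.05;
5. compares young and aged decay rates with the standard score
   Z = (λ_Y − λ_A)/(SE_Y + SE_A), Bonferroni-corrected, and classifies
   each shared transcript as unchanged / shorter-in-aged / longer-in-aged
   by a 1-hour half-life difference rule;
6. computes sequence features (GC/AU content, IUPAC S/W codon-class
   fractions, 61 sense-codon frequencies, a Kozak PWM score), binned
   **codon stability coefficients** (CSC: per-codon Pearson correlation of
   codon frequency with half-life inside 1-h bins of the young half-life
   axis, values in (−0.1, 0.1) filtered before averaging; positive mean ⇒
   optimal codon), the **protein abundance codon correlation** (PACC:
   per-codon Spearman correlation of codon frequency with the iBAQ
   MII−GV change across single-protein-group genes), and the
   cross-correlations that detect an age-dependent inversion of the
   GC-content/stability rules.

A fully deterministic synthetic-data generator (`simulateStudy`) produces
transcript FASTA, kallisto-style abundance tables and a protein table with
known ground truth, so every stage is testable end to end without any
download. See the methods vignette
(`vignettes/maternal-mrna-decay.Rmd`) for the statistical details and
design choices.

## Worked example

Simulate a cohort under the default study conditions (5 replicates per
stage and age group, 24 h maturation window, replicate noise CV 0.2, an
age-dependent inversion of the GC–stability coupling) and run the whole
pipeline:

```r
library(oocyteDecay)

dir <- file.path(tempdir(), "demo")
cfg <- simulationConfig(nTranscripts = 1000, seed = 42)
study <- simulateStudy(cfg, dir = dir)

out <- file.path(dir, "results")
pcfg <- pipelineConfig(referenceFasta = study$paths$fasta,
                       metadata = study$paths$metadata,
                       proteinTable = study$paths$protein,
                       outDir = out, requireSignificance = FALSE)
manifest <- runPipeline(pcfg)

readResultTable(file.path(out, "category_summary.tsv"))
#>          category   n median_young_h median_aged_h        ks_p
#> 1       unchanged 366        6.55441       6.56316 9.89320e-01
#> 2 shorter_in_aged 314       14.10700       8.83683 2.95319e-14
#> 3  longer_in_aged 196        8.23683      13.25830 1.13560e-10

readResultTable(file.path(out, "rna_protein.tsv"))
#>                  quantity     value   n
#> 1 profile_correlation_rho -0.874097  18
#> 2 csc_pacc_rho_unaffected -0.545540  60
#> 3   csc_pacc_rho_affected  0.860233  61
#> 4   half_life_protein_rho -0.640449 830
```

Reading the output: 876 of the 1000 transcripts were compared in both age
groups and partition into the three change categories, with the expected
median shifts (e.g. 14.1 h → 8.8 h for transcripts destabilized with age;
the KS p-values confirm the paired distributions differ). The feature
profiles of the two arms correlate at ρ = −0.87 — the engineered inversion
of the sequence/stability rules — and the CSC–PACC correlation flips sign
between arms (−0.55 unaffected vs +0.86 affected). In the affected arm all
32 optimal codons are GC-rich, while the unaffected arm's optimal codons
are AU-dominated:

```r
csc <- readResultTable(file.path(out, "csc_affected.tsv"))
opt <- csc[!is.na(csc$optimal) & csc$optimal, ]
sum(sapply(strsplit(opt$codon, ""), function(b) sum(b %in% c("G","C")) >= 2))
#> [1] 32
```

Every output table carries a provenance header (package version +
configuration hash), and `manifest.json` records per-stage record counts.

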