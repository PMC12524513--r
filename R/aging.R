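# Group-level summaries: half-life distributions per category, binned
# feature/half-life correlation profiles, correlation of profiles between
# arms, and RNA-protein comparisons.

# Feature columns entering correlation profiles: everything numeric except
# identifiers, per-codon frequencies and bookkeeping flags.
.profile_features <- function(features) {
  drop <- c("transcript_id", "gene_id", "n_internal_stops")
  keep <- setdiff(colnames(features), drop)
  keep[!startsWith(keep, "codon_") &
         vapply(features[keep], is.numeric, logical(1))]
}

#' Summarize half-life distributions per change category
#'
#' Counts and median young/aged half-lives per category, with a two-sample
#' two-sided Kolmogorov-Smirnov test between the paired young and aged
#' distributions of each category.
#'
#' @param comparisons classified data.frame from [classifyChange()].
#' @return data.frame with `category`, `n`, `median_young_h`,
#'   `median_aged_h`, `ks_p`.
#' @export
summarizeHalfLives <- function(comparisons) {
  stopifnot("category" %in% colnames(comparisons))
  d <- comparisons[!is.na(comparisons$category), ]
  cats <- levels(d$category)
  rows <- lapply(cats, function(cc) {
    s <- d[d$category == cc, ]
    ks <- if (nrow(s) >= 2L)
      suppressWarnings(stats::ks.test(s$half_life_h_young,
                                      s$half_life_h_aged))$p.value
    else NA_real_
    data.frame(category = cc, n = nrow(s),
               median_young_h = stats::median(s$half_life_h_young),
               median_aged_h = stats::median(s$half_life_h_aged),
               ks_p = ks)
  })
  do.call(rbind, rows)
}

#' Binned feature/half-life correlation profile
#'
#' Within every half-life bin of at least `minBinSize` members, computes
#' the Spearman correlation of each sequence feature with the arm's
#' response half-life, then averages over bins (mean and SEM). Features
#' with zero variance in a bin skip that bin. Per-codon frequency columns
#' are excluded (codon-level analysis lives in [cscPerBin()]).
#'
#' @param bins data.frame from [binByYoungHalfLife()].
#' @param features data.frame from [buildFeatureTable()].
#' @param minBinSize minimum bin occupancy (default 20).
#' @return data.frame with `feature`, `mean_rho`, `sem_rho`, `n_bins`.
#' @export
featureHalfLifeCorrelations <- function(bins, features, minBinSize = 20L) {
  feat_cols <- .profile_features(features)
  fm <- as.matrix(features[, feat_cols, drop = FALSE])
  rownames(fm) <- features$transcript_id
  missing_ids <- setdiff(bins$transcript_id, rownames(fm))
  if (length(missing_ids))
    stop("features missing for ", length(missing_ids), " binned transcript(s)")
  acc <- matrix(NA_real_, nrow = 0L, ncol = length(feat_cols),
                dimnames = list(NULL, feat_cols))
  for (b in sort(unique(bins$bin_index))) {
    members <- bins[bins$bin_index == b, ]
    if (nrow(members) < minBinSize) next
    f <- fm[members$transcript_id, , drop = FALSE]
    r <- suppressWarnings(as.vector(
      stats::cor(f, members$response, method = "spearman")))
    acc <- rbind(acc, r)
  }
  data.frame(
    feature = feat_cols,
    mean_rho = apply(acc, 2L, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    }),
    sem_rho = apply(acc, 2L, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
      else if (length(v) == 1L) 0 else NA_real_
    }),
    n_bins = apply(acc, 2L, function(v) sum(is.finite(v))),
    row.names = NULL)
}

#' Correlate two feature profiles
#'
#' Spearman correlation between the per-feature mean correlations of two
#' analysis arms (e.g. age-unaffected vs age-affected transcripts). A
#' strongly negative value indicates an inversion of the sequence/stability
#' rules between arms.
#'
#' @param p1,p2 data.frames from [featureHalfLifeCorrelations()].
#' @return list with `rho`, `p` and `n` (features in common).
#' @export
correlationOfProfiles <- function(p1, p2) {
  m <- merge(p1[, c("feature", "mean_rho")], p2[, c("feature", "mean_rho")],
             by = "feature", suffixes = c("_1", "_2"))
  m <- m[is.finite(m$mean_rho_1) & is.finite(m$mean_rho_2), ]
  if (nrow(m) < 5L) stop("fewer than 5 features in common between profiles")
  ct <- suppressWarnings(stats::cor.test(m$mean_rho_1, m$mean_rho_2,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

# Restrict a protein table to single-protein-group genes and return the
# named iBAQ delta vector.
.protein_deltas <- function(proteinTable) {
  s <- proteinTable[proteinTable$n_protein_groups == 1L, ]
  stats::setNames(s$ibaq_mii - s$ibaq_gv, s$gene_id)
}

# Map per-transcript values to genes (mean over a gene's transcripts).
.per_gene <- function(values, transcript_id, geneMap) {
  g <- geneMap$gene_id[match(transcript_id, geneMap$transcript_id)]
  ok <- !is.na(g) & is.finite(values)
  tapply(values[ok], g[ok], mean)
}

#' Correlate young half-life with the protein abundance change
#'
#' Spearman correlation between the reproductively young half-life and the
#' iBAQ MII - GV difference across single-protein-group genes.
#'
#' @param fitsYoung data.frame from [fitAllDecay()] for the young group.
#' @param proteinTable data.frame from [readProteinTable()].
#' @param geneMap data.frame with `transcript_id`, `gene_id`.
#' @return list with `rho`, `p`, `n` and `flagged` (TRUE when n < 10).
#' @export
proteinHalfLifeCorrelation <- function(fitsYoung, proteinTable, geneMap) {
  fits <- fitsYoung[if ("decay_fit" %in% colnames(fitsYoung))
    fitsYoung$decay_fit else TRUE, ]
  hl <- .per_gene(fits$half_life_h, fits$transcript_id, geneMap)
  delta <- .protein_deltas(proteinTable)
  common <- intersect(names(hl), names(delta))
  flagged <- length(common) < 10L
  if (flagged)
    warning("fewer than 10 genes in the RNA-protein intersection")
  if (length(common) < 3L)
    return(list(rho = NA_real_, p = NA_real_, n = length(common),
                flagged = TRUE))
  ct <- suppressWarnings(stats::cor.test(hl[common], delta[common],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common),
       flagged = flagged)
}

#' Correlate features with the protein abundance change per category
#'
#' For each half-life change category (stability lost: `shorter_in_aged`;
#' stability gained: `longer_in_aged`), the Spearman correlation of every
#' sequence feature with the iBAQ MII - GV difference across
#' single-protein-group genes. Categories with fewer than 10 genes give an
#' `NA` row with a warning.
#'
#' @param features data.frame from [buildFeatureTable()].
#' @param proteinTable data.frame from [readProteinTable()].
#' @param comparisons classified data.frame from [classifyChange()].
#' @param geneMap data.frame with `transcript_id`, `gene_id`.
#' @return data.frame with `category`, `feature`, `rho`, `n`.
#' @export
proteinFeatureCorrelations <- function(features, proteinTable, comparisons,
                                       geneMap) {
  delta <- .protein_deltas(proteinTable)
  feat_cols <- .profile_features(features)
  cats <- c("shorter_in_aged", "longer_in_aged")
  rows <- lapply(cats, function(cc) {
    tx <- comparisons$transcript_id[!is.na(comparisons$category) &
                                      comparisons$category == cc]
    sel <- features[features$transcript_id %in% tx, , drop = FALSE]
    per_gene <- lapply(feat_cols, function(fc)
      .per_gene(sel[[fc]], sel$transcript_id, geneMap))
    genes <- if (nrow(sel)) intersect(names(per_gene[[1]]), names(delta))
             else character()
    if (length(genes) < 10L) {
      warning("category ", cc, " has fewer than 10 genes with protein data")
      return(data.frame(category = cc, feature = feat_cols, rho = NA_real_,
                        n = length(genes)))
    }
    rho <- vapply(per_gene, function(v)
      suppressWarnings(stats::cor(v[genes], delta[genes],
                                  method = "spearman")), numeric(1))
    data.frame(category = cc, feature = feat_cols, rho = rho,
               n = length(genes))
  })
  do.call(rbind, rows)
}
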