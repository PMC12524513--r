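# Codon stability coefficients (CSC) and the protein abundance codon
# correlation (PACC). CSC is computed within 1-h bins of the young
# half-life axis (Pearson, as in the classic codon-optimality analyses);
# all cross-variable summaries are Spearman.

#' Bin compared transcripts by young half-life
#'
#' Builds the 1-h, half-open `[k, k+1)` bins on the reproductively young
#' half-life axis used by the binned feature and CSC analyses. The
#' `unaffected` arm keeps transcripts whose category is `unchanged` and
#' carries their young half-life as the response; the `affected` arm keeps
#' the two changed categories (those that moved by more than the
#' classification threshold) and carries their aged half-life as the
#' response.
#'
#' @param comparisons classified data.frame from [classifyChange()].
#' @param arm `"unaffected"` or `"affected"`.
#' @param widthH bin width in hours (default 1).
#' @return data.frame with `transcript_id`, `bin_index` (bin lower edge is
#'   `bin_index * widthH`), `response` (the arm's half-life in hours) and
#'   both half-lives.
#' @export
binByYoungHalfLife <- function(comparisons, arm = c("unaffected", "affected"),
                               widthH = 1.0) {
  arm <- match.arg(arm)
  stopifnot("category" %in% colnames(comparisons))
  keep <- if (arm == "unaffected") {
    comparisons$category %in% "unchanged"
  } else {
    comparisons$category %in% c("shorter_in_aged", "longer_in_aged")
  }
  d <- comparisons[keep & is.finite(comparisons$half_life_h_young) &
                     is.finite(comparisons$half_life_h_aged), ]
  data.frame(
    transcript_id = d$transcript_id,
    bin_index = as.integer(floor(d$half_life_h_young / widthH)),
    response = if (arm == "unaffected") d$half_life_h_young
               else d$half_life_h_aged,
    half_life_h_young = d$half_life_h_young,
    half_life_h_aged = d$half_life_h_aged,
    row.names = NULL)
}

#' Per-bin codon stability coefficients
#'
#' Within every half-life bin of at least `minBinSize` members, correlates
#' each sense codon's frequency with the member half-lives (Pearson).
#' Codons with zero variance within a bin give `NA`; undersized bins are
#' skipped.
#'
#' @param bins data.frame from [binByYoungHalfLife()].
#' @param codonFreq numeric matrix of codon frequencies (transcripts x
#'   codons) with transcript ids as row names, e.g. from
#'   [codonFrequencies()].
#' @param minBinSize minimum bin occupancy (default 20).
#' @return data.frame with `bin_index`, `codon`, `r` and `n` (bin size).
#' @export
cscPerBin <- function(bins, codonFreq, minBinSize = 20L) {
  missing_ids <- setdiff(bins$transcript_id, rownames(codonFreq))
  if (length(missing_ids))
    stop("codon frequencies missing for ", length(missing_ids),
         " binned transcript(s)")
  out <- list()
  for (b in sort(unique(bins$bin_index))) {
    members <- bins[bins$bin_index == b, ]
    if (nrow(members) < minBinSize) next
    f <- codonFreq[members$transcript_id, , drop = FALSE]
    r <- suppressWarnings(as.vector(stats::cor(f, members$response)))
    out[[length(out) + 1L]] <- data.frame(
      bin_index = b, codon = colnames(codonFreq), r = r, n = nrow(members),
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(bin_index = integer(), codon = character(),
                      r = numeric(), n = integer()))
  do.call(rbind, out)
}

#' Aggregate per-bin CSC values into per-codon statistics
#'
#' Per-bin values strictly inside `filterBand` (default `(-0.1, 0.1)`) are
#' filtered out prior to averaging; the rest are averaged with
#' `SEM = sd / sqrt(n)` over the bins used. A codon is called optimal when
#' its mean CSC is positive. With an empty band `c(0, 0)` the result is
#' the plain mean over bins.
#'
#' @param perBin data.frame from [cscPerBin()].
#' @param filterBand numeric length-2: the open interval of CSC values
#'   dropped before averaging.
#' @return data.frame with one row per codon: `codon`, `mean_csc`,
#'   `sem_csc`, `n_bins_used`, `optimal`.
#' @export
aggregateCsc <- function(perBin, filterBand = c(-0.1, 0.1)) {
  stopifnot(length(filterBand) == 2L, filterBand[1] <= filterBand[2])
  codons <- unique(perBin$codon)
  rows <- lapply(codons, function(cc) {
    r <- perBin$r[perBin$codon == cc]
    r <- r[!is.na(r)]
    r <- r[!(r > filterBand[1] & r < filterBand[2])]
    n <- length(r)
    data.frame(
      codon = cc,
      mean_csc = if (n) mean(r) else NA_real_,
      sem_csc = if (n > 1L) stats::sd(r) / sqrt(n) else
        if (n == 1L) 0 else NA_real_,
      n_bins_used = n,
      optimal = if (n) mean(r) > 0 else NA)
  })
  do.call(rbind, rows)
}

#' Protein abundance codon correlation (PACC)
#'
#' Per codon, the Spearman correlation between codon frequency and the
#' GV-to-MII protein abundance change (iBAQ MII - GV) across genes.
#' Restrict the inputs to single-protein-group genes before calling.
#'
#' @param codonFreq numeric matrix of codon frequencies with gene ids as
#'   row names (one representative transcript per gene).
#' @param proteinDelta named numeric vector of iBAQ MII - GV differences.
#' @return data.frame with `codon`, `pacc` and `n` (genes used).
#' @export
pacc <- function(codonFreq, proteinDelta) {
  common <- intersect(rownames(codonFreq), names(proteinDelta))
  if (length(common) < 10L)
    stop("fewer than 10 genes shared between codon frequencies and ",
         "protein deltas; PACC is uninterpretable")
  f <- codonFreq[common, , drop = FALSE]
  d <- proteinDelta[common]
  r <- suppressWarnings(as.vector(
    stats::cor(f, d, method = "spearman", use = "everything")))
  data.frame(codon = colnames(codonFreq), pacc = r, n = length(common),
             row.names = NULL)
}

#' Correlate mean CSC with PACC across codons
#'
#' Spearman correlation between the per-codon mean CSC of one analysis arm
#' and the per-codon PACC, over the codons where both are defined.
#'
#' @param cscStats data.frame from [aggregateCsc()].
#' @param paccTable data.frame from [pacc()].
#' @return list with `rho`, `p` (two-sided) and `n` (codons in common).
#' @export
cscVsPacc <- function(cscStats, paccTable) {
  m <- merge(cscStats[, c("codon", "mean_csc")],
             paccTable[, c("codon", "pacc")], by = "codon")
  m <- m[is.finite(m$mean_csc) & is.finite(m$pacc), ]
  if (nrow(m) < 10L)
    stop("fewer than 10 codons with both CSC and PACC defined")
  ct <- suppressWarnings(stats::cor.test(m$mean_csc, m$pacc,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
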