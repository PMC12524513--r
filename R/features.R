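# Per-transcript sequence features: region lengths, GC/AU content, IUPAC
# S/W codon-class fractions, sense-codon frequencies and the Kozak context
# score. U is treated as T throughout; inputs are normalized on read.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"))[, 3:1],
                          1L, paste, collapse = ""))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)
.CODON_CLASSES <- c("nnS", "nSS", "SSn", "SSS", "nnW", "nWW", "WWn", "WWW")

.as_dna <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(chartr("Uu", "Tt", x))
  x
}

#' Codon-class indicator matrix
#'
#' Indicator of the eight IUPAC S/W codon-class patterns over the 64-codon
#' alphabet, where S is G or C, W is A or T, and n matches any base. The
#' patterns overlap by design: a codon such as GCG matches SSS, SSn, nSS
#' and nnS simultaneously. Over all 64 codons the column sums are 8 (SSS),
#' 16 (SSn), 16 (nSS), 32 (nnS) and the W mirrors.
#'
#' @return 64 x 8 logical matrix; rows named by codon, columns by class.
#' @examples
#' colSums(codonClassMatrix())
#' @export
codonClassMatrix <- function() {
  bases <- strsplit(.ALL_CODONS, "")
  s <- vapply(bases, function(b) b %in% c("G", "C"), logical(3))
  w <- !s
  m <- cbind(
    nnS = s[3, ], nSS = s[2, ] & s[3, ], SSn = s[1, ] & s[2, ],
    SSS = s[1, ] & s[2, ] & s[3, ],
    nnW = w[3, ], nWW = w[2, ] & w[3, ], WWn = w[1, ] & w[2, ],
    WWW = w[1, ] & w[2, ] & w[3, ])
  rownames(m) <- .ALL_CODONS
  m
}

# Strip a terminal stop codon where present; widths stay multiples of 3.
.strip_terminal_stop <- function(cds) {
  w <- Biostrings::width(cds)
  last <- as.character(Biostrings::subseq(cds, start = pmax(w - 2L, 1L),
                                          end = w))
  has_stop <- w >= 3L & last %in% .STOP_CODONS
  if (any(has_stop))
    cds[has_stop] <- Biostrings::subseq(cds[has_stop], start = 1L,
                                        end = w[has_stop] - 3L)
  cds
}

# In-frame codon counts over the 64-codon alphabet; codons containing N are
# not counted (trinucleotideFrequency skips ambiguous letters).
.codon_counts <- function(cds, stripStop = TRUE) {
  cds <- .as_dna(cds)
  if (any(Biostrings::width(cds) %% 3L != 0L))
    stop("CDS lengths must be multiples of 3")
  if (stripStop) cds <- .strip_terminal_stop(cds)
  cnt <- Biostrings::trinucleotideFrequency(cds, step = 3L)
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L,
                                       dimnames = list(NULL, names(cnt)))
  rownames(cnt) <- names(cds)
  cnt[, .ALL_CODONS, drop = FALSE]
}

#' GC and AU content of nucleotide sequences
#'
#' `gcContent()` returns (#G + #C) / (#A + #C + #G + #T); `auContent()` the
#' A/T complement. N bases are excluded from both numerator and
#' denominator; empty or all-N sequences give `NA`.
#'
#' @param x character vector or [Biostrings::DNAStringSet] (U allowed).
#' @return numeric vector of fractions in `[0, 1]` (or `NA`).
#' @examples
#' gcContent(c("GCGC", "ATAT", "ATGC"))
#' @export
gcContent <- function(x) {
  x <- .as_dna(x)
  f <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  denom <- rowSums(f)
  ifelse(denom > 0, (f[, "G"] + f[, "C"]) / denom, NA_real_)
}

#' @rdname gcContent
#' @export
auContent <- function(x) {
  x <- .as_dna(x)
  f <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  denom <- rowSums(f)
  ifelse(denom > 0, (f[, "A"] + f[, "T"]) / denom, NA_real_)
}

#' IUPAC S/W codon-class fractions of coding sequences
#'
#' For each of the eight overlapping patterns (`nnS`, `nSS`, `SSn`, `SSS`
#' and the W mirrors) returns the fraction of CDS codons matching it.
#' A terminal stop codon is stripped first and stop codons are excluded
#' from numerator and denominator (the analysis alphabet is the 61 sense
#' codons); codons containing N are excluded as well.
#'
#' @param cds character vector or DNAStringSet of CDS (lengths multiples
#'   of 3).
#' @return numeric matrix, transcripts x 8 classes.
#' @examples
#' codonClassFractions("ATGGCC")["1", "SSS"]  # GCC matches SSS
#' @export
codonClassFractions <- function(cds) {
  cnt <- .codon_counts(cds)[, .SENSE_CODONS, drop = FALSE]
  ind <- codonClassMatrix()[.SENSE_CODONS, , drop = FALSE]
  denom <- rowSums(cnt)
  frac <- (cnt %*% ind) / denom
  frac[denom == 0, ] <- NA_real_
  if (is.null(rownames(frac))) rownames(frac) <- as.character(seq_len(nrow(frac)))
  frac
}

#' Sense-codon frequencies of coding sequences
#'
#' Counts in-frame codons over the 61 sense codons, normalized to sum to 1
#' per transcript. A terminal stop codon is removed when present; internal
#' stop codons are not counted but their number is reported in the
#' `"n_internal_stops"` attribute so affected transcripts can be flagged.
#'
#' @inheritParams codonClassFractions
#' @return numeric matrix, transcripts x 61 sense codons, rows summing
#'   to 1 (NA rows when no sense codon is present); attribute
#'   `n_internal_stops` is an integer vector per transcript.
#' @examples
#' codonFrequencies("ATGGCCTAA")  # terminal TAA removed: ATG 0.5, GCC 0.5
#' @export
codonFrequencies <- function(cds) {
  cnt <- .codon_counts(cds)
  n_stop <- as.integer(rowSums(cnt[, .STOP_CODONS, drop = FALSE]))
  sense <- cnt[, .SENSE_CODONS, drop = FALSE]
  denom <- rowSums(sense)
  freq <- sense / denom
  freq[denom == 0, ] <- NA_real_
  if (is.null(rownames(freq))) rownames(freq) <- as.character(seq_len(nrow(freq)))
  attr(freq, "n_internal_stops") <- stats::setNames(n_stop, rownames(freq))
  freq
}

# --- Kozak scoring ----------------------------------------------------------

.KOZAK_MOTIF <- "RYMRMVATGGC"
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
               V = c("A", "C", "G"))

# Position weight matrix (log2 odds vs uniform background) for the Kozak
# consensus: allowed bases share probability uniformly, disallowed bases get
# pseudo-probability 0.001, columns renormalized.
.kozak_pwm <- function() {
  letters_ <- strsplit(.KOZAK_MOTIF, "")[[1]]
  pwm <- vapply(letters_, function(l) {
    allowed <- .IUPAC[[l]]
    p <- rep(0.001, 4)
    names(p) <- c("A", "C", "G", "T")
    p[allowed] <- 1 / length(allowed)
    p <- p / sum(p)
    log2(p / 0.25)
  }, numeric(4))
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm
}

#' Score the Kozak context of annotated start codons
#'
#' Builds the 11-nt context around the start codon (the last 6 nt of the
#' 5' UTR followed by the first 5 nt of the CDS, so the annotated ATG is
#' anchored at motif positions 7-9) and scores it against a position
#' weight matrix derived from the consensus `RYMRMVATGGC`: allowed bases
#' share probability uniformly, disallowed bases get pseudo-probability
#' 0.001 (renormalized), and the per-position log2 odds against a uniform
#' background are summed. UTRs shorter than 6 nt are padded with N, which
#' contributes 0. The raw score is mapped to `[0, 1]` as
#' `(score - min) / (max - min)` over the achievable range, so a consensus
#' word scores exactly 1.
#'
#' @param utr5 character vector or DNAStringSet of 5' UTRs (may be empty).
#' @param cds character vector or DNAStringSet of CDS; each should start
#'   with ATG (scored as-is regardless).
#' @return numeric vector of normalized scores in `[0, 1]`.
#' @examples
#' kozakScore("GCAGCC", "ATGGCCTAA")  # consensus context, score 1
#' @export
kozakScore <- function(utr5, cds) {
  utr5 <- as.character(.as_dna(utr5))
  cds <- as.character(.as_dna(cds))
  stopifnot(length(utr5) == length(cds))
  pad <- function(s, n, left) {
    k <- nchar(s)
    if (k >= n) {
      if (left) substr(s, k - n + 1L, k) else substr(s, 1L, n)
    } else {
      padding <- strrep("N", n - k)
      if (left) paste0(padding, s) else paste0(s, padding)
    }
  }
  up <- vapply(utr5, pad, character(1), n = 6L, left = TRUE,
               USE.NAMES = FALSE)
  down <- vapply(cds, pad, character(1), n = 5L, left = FALSE,
                 USE.NAMES = FALSE)
  ctx <- toupper(paste0(up, down))
  pwm <- .kozak_pwm()
  lo <- apply(pwm, 2L, min)
  hi <- apply(pwm, 2L, max)
  chars <- matrix(unlist(strsplit(ctx, "")), nrow = 11L)
  score <- vapply(seq_along(ctx), function(i) {
    s <- 0
    for (p in 1:11) {
      b <- chars[p, i]
      if (b %in% rownames(pwm)) s <- s + pwm[b, p]
    }
    s
  }, numeric(1))
  (score - sum(lo)) / (sum(hi) - sum(lo))
}

#' Build the per-transcript feature table
#'
#' Assembles every sequence feature into one data.frame: region lengths,
#' GC/AU content per region (NA for absent regions), the eight codon-class
#' fractions, the Kozak score, the internal-stop flag and the 61
#' sense-codon frequencies (columns prefixed `codon_`).
#'
#' @param ts A [TranscriptSet-class].
#' @return data.frame with one row per transcript, deterministic column
#'   order, `transcript_id` and `gene_id` first.
#' @export
buildFeatureTable <- function(ts) {
  stopifnot(is(ts, "TranscriptSet"))
  cds <- cdsSeq(ts)
  u5 <- utr5Seq(ts)
  u3 <- utr3Seq(ts)
  cls <- codonClassFractions(cds)
  freq <- codonFrequencies(cds)
  out <- data.frame(
    transcript_id = transcriptId(ts),
    gene_id = geneId(ts),
    cds_length = Biostrings::width(cds),
    utr5_length = Biostrings::width(u5),
    utr3_length = Biostrings::width(u3),
    gc_cds = gcContent(cds), gc_utr5 = gcContent(u5), gc_utr3 = gcContent(u3),
    au_cds = auContent(cds), au_utr5 = auContent(u5), au_utr3 = auContent(u3),
    row.names = NULL)
  out <- cbind(out, as.data.frame(cls, row.names = NULL))
  out$kozak_score <- kozakScore(u5, cds)
  out$n_internal_stops <- unname(attr(freq, "n_internal_stops"))
  freq_df <- as.data.frame(freq, row.names = NULL)
  colnames(freq_df) <- paste0("codon_", colnames(freq_df))
  cbind(out, freq_df)
}
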