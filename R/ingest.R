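# Reading the standard input formats and the expression filter that defines
# the analysis universe.

# Parse one GENCODE-style pipe-delimited FASTA header into its segments.
# Returns list(transcript_id, gene_id, utr5, cds, utr3) where the regions are
# c(start, end) 1-based inclusive or NULL when absent; NULL on malformed ids.
.parse_gencode_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  fields <- fields[nzchar(fields)]
  if (length(fields) < 1L) return(NULL)
  out <- list(transcript_id = fields[1],
              gene_id = if (length(fields) >= 2L &&
                            !grepl(":", fields[2])) fields[2] else NA_character_,
              utr5 = NULL, cds = NULL, utr3 = NULL)
  seg <- grep("^(UTR5|CDS|UTR3):[0-9]+-[0-9]+$", fields, value = TRUE)
  for (s in seg) {
    key <- tolower(sub(":.*", "", s))
    rng <- as.integer(strsplit(sub(".*:", "", s), "-", fixed = TRUE)[[1]])
    if (rng[1] < 1L || rng[2] < rng[1]) return(NULL)
    out[[key]] <- rng
  }
  out
}

#' Read a transcript reference FASTA with GENCODE-style headers
#'
#' Parses a protein-coding transcript FASTA whose pipe-delimited headers
#' carry `UTR5:a-b`, `CDS:a-b` and `UTR3:a-b` segments (1-based, inclusive,
#' GENCODE convention) and extracts the region sequences. Records without a
#' CDS segment, or whose CDS length is not a multiple of 3, are dropped; the
#' number of drops is reported via a message. Malformed headers are skipped
#' with a warning.
#'
#' @param path FASTA file path.
#' @return A [TranscriptSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">ENST0A|GENEA|UTR5:1-3|CDS:4-9|UTR3:10-12|",
#'              "AAAATGGCCTTT"), fa)
#' ts <- readTranscriptReference(fa)
#' as.character(cdsSeq(ts))
#' @export
readTranscriptReference <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA reference: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  keep_id <- character()
  keep_gene <- character()
  cds <- utr5 <- utr3 <- character()
  n_dropped <- 0L
  n_malformed <- 0L
  for (i in seq_along(seqs)) {
    h <- .parse_gencode_header(headers[i])
    if (is.null(h) || is.na(h$transcript_id) || !nzchar(h$transcript_id)) {
      n_malformed <- n_malformed + 1L
      next
    }
    s <- as.character(seqs[[i]])
    if (is.null(h$cds) || h$cds[2] > nchar(s) ||
        (h$cds[2] - h$cds[1] + 1L) %% 3L != 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    sub_or_empty <- function(rng) {
      if (is.null(rng)) "" else substr(s, rng[1], rng[2])
    }
    keep_id <- c(keep_id, h$transcript_id)
    keep_gene <- c(keep_gene, h$gene_id)
    cds <- c(cds, sub_or_empty(h$cds))
    utr5 <- c(utr5, sub_or_empty(h$utr5))
    utr3 <- c(utr3, sub_or_empty(h$utr3))
  }
  if (n_malformed > 0L)
    warning(n_malformed, " record(s) skipped due to malformed headers")
  if (n_dropped > 0L)
    message(n_dropped,
            " record(s) dropped: CDS absent or length not a multiple of 3")
  if (anyDuplicated(keep_id))
    stop("duplicate transcript ids in reference: ",
         paste(unique(keep_id[duplicated(keep_id)]), collapse = ", "))
  TranscriptSet(keep_id, keep_gene, cds, utr5, utr3)
}

#' Read per-sample transcript abundance tables into a DecayExperiment
#'
#' Reads kallisto-style abundance TSVs (columns `target_id` and `tpm` at
#' minimum) and assembles a transcripts x samples matrix over the union of
#' transcript ids. Ids absent from a table get value 0 with a warning
#' giving the fill count. Transcript ids are matched exactly by default;
#' `stripVersion = TRUE` removes a trailing `.N` version suffix first
#' (versioned ids are never merged silently).
#'
#' @param paths character vector of abundance TSV paths, one per sample.
#' @param sampleData data.frame with one row per path: `sample_id`,
#'   `stage` (GV/MII), `age_group` (young/aged), `time_h`.
#' @param stripVersion strip trailing transcript version suffixes?
#' @return A [DecayExperiment-class] with assay `"tpm"`.
#' @export
readAbundance <- function(paths, sampleData, stripVersion = FALSE) {
  sampleData <- as.data.frame(sampleData)
  if (length(paths) != nrow(sampleData))
    stop("one abundance table per sampleData row is required")
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("cannot read abundance table: ", p)
    tab <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("target_id", "tpm") %in% colnames(tab)))
      stop("abundance table lacks target_id/tpm columns: ", p)
    ids <- as.character(tab$target_id)
    if (stripVersion) ids <- sub("\\.[0-9]+$", "", ids)
    if (anyDuplicated(ids))
      stop("duplicate transcript id within one table: ", p)
    stats::setNames(as.numeric(tab$tpm), ids)
  })
  universe <- Reduce(union, lapply(tabs, names))
  values <- vapply(tabs, function(v) {
    out <- v[universe]
    out[is.na(out)] <- 0
    unname(out)
  }, numeric(length(universe)))
  values <- matrix(values, nrow = length(universe), ncol = length(tabs))
  n_fill <- sum(vapply(tabs, function(v) sum(!universe %in% names(v)),
                       integer(1)))
  if (n_fill > 0L)
    warning(n_fill, " (transcript, sample) cells absent from their table; ",
            "filled with 0")
  rownames(values) <- universe
  DecayExperiment(values, sampleData)
}

#' Filter to transcripts expressed in every sample
#'
#' Keeps exactly the transcripts with abundance `>= minTpm` in every sample
#' of the experiment. When young and aged groups are analyzed separately,
#' subset the experiment per age group first so the filter applies per group
#' independently.
#'
#' @param x A [DecayExperiment-class].
#' @param minTpm expression threshold in TPM (default 1; 0 keeps all).
#' @return The filtered [DecayExperiment-class].
#' @export
filterExpressed <- function(x, minTpm = 1.0) {
  stopifnot(is(x, "DecayExperiment"))
  keep <- rowSums(SummarizedExperiment::assay(x) >= minTpm) == ncol(x)
  if (!any(keep))
    warning("no transcript passes the expression filter")
  x[keep, ]
}

#' Read a protein abundance (iBAQ) table
#'
#' Expects a TSV with a gene id column, a protein-group count column and one
#' or more iBAQ columns per condition (matched as `ibaq_gv*` and
#' `ibaq_mii*`, case-insensitive). Replicate iBAQ columns are averaged per
#' condition; zeros are retained. Genes with more than one protein group are
#' kept in the output but must be excluded from RNA-protein analyses
#' (downstream functions do this via `n_protein_groups`).
#'
#' @param path TSV path with columns `gene_id`, `n_protein_groups`,
#'   `ibaq_gv...`, `ibaq_mii...`.
#' @return data.frame with `gene_id`, `n_protein_groups`, `ibaq_gv`,
#'   `ibaq_mii`.
#' @export
readProteinTable <- function(path) {
  if (!file.exists(path)) stop("cannot read protein table: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("protein table is empty")
    return(data.frame(gene_id = character(), n_protein_groups = integer(),
                      ibaq_gv = numeric(), ibaq_mii = numeric()))
  }
  if (!all(c("gene_id", "n_protein_groups") %in% colnames(tab)))
    stop("protein table lacks gene_id/n_protein_groups columns")
  gv_cols <- grep("^ibaq_gv", colnames(tab), ignore.case = TRUE, value = TRUE)
  mii_cols <- grep("^ibaq_mii", colnames(tab), ignore.case = TRUE, value = TRUE)
  if (!length(gv_cols) || !length(mii_cols))
    stop("protein table lacks ibaq_gv*/ibaq_mii* columns")
  gv <- rowMeans(as.matrix(tab[, gv_cols, drop = FALSE]))
  mii <- rowMeans(as.matrix(tab[, mii_cols, drop = FALSE]))
  if (any(gv < 0, na.rm = TRUE) || any(mii < 0, na.rm = TRUE))
    stop("negative iBAQ values are not allowed")
  data.frame(gene_id = as.character(tab$gene_id),
             n_protein_groups = as.integer(tab$n_protein_groups),
             ibaq_gv = gv, ibaq_mii = mii)
}
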