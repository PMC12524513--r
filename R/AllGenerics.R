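#' Accessors for TranscriptSet
#'
#' `cdsSeq()`, `utr5Seq()` and `utr3Seq()` return the region sequences as
#' [Biostrings::DNAStringSet]; `transcriptId()` and `geneId()` return the
#' identifier vectors.
#'
#' @param x A [TranscriptSet-class].
#' @return A DNAStringSet or character vector parallel to the transcripts.
#' @name TranscriptSet-accessors
#' @examples
#' ts <- TranscriptSet("tx1", "gene1", cds = "ATGGCC")
#' transcriptId(ts)
NULL

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("utr5Seq", function(x) standardGeneric("utr5Seq"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("utr3Seq", function(x) standardGeneric("utr3Seq"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname TranscriptSet-accessors
setMethod("cdsSeq", "TranscriptSet", function(x) x@cds)
#' @rdname TranscriptSet-accessors
setMethod("utr5Seq", "TranscriptSet", function(x) x@utr5)
#' @rdname TranscriptSet-accessors
setMethod("utr3Seq", "TranscriptSet", function(x) x@utr3)
#' @rdname TranscriptSet-accessors
setMethod("transcriptId", "TranscriptSet", function(x) names(x@cds))
#' @rdname TranscriptSet-accessors
setMethod("geneId", "TranscriptSet", function(x) x@geneId)

#' @describeIn TranscriptSet-accessors number of transcripts.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@cds))

#' Subset a TranscriptSet
#'
#' @param x A [TranscriptSet-class].
#' @param i integer, logical or character (transcript id) index.
#' @param j,...,drop ignored.
#' @return A TranscriptSet restricted to the selected transcripts.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@cds))
  initialize(x, cds = x@cds[i], utr5 = x@utr5[i], utr3 = x@utr3[i],
             geneId = x@geneId[i])
})
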