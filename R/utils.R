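# Internal helpers shared across modules.

# Significant-digit formatting used by all result writers; NA -> "NA".
.format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.infinite(v)) return(ifelse(v > 0, "Inf", "-Inf"))
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

# Deterministic md5 of an arbitrary R object via its deparsed form.
.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

.stages <- c("GV", "MII")
.age_groups <- c("young", "aged")

.assert_one_age_group <- function(x, what) {
  ag <- unique(SummarizedExperiment::colData(x)$age_group)
  if (length(ag) != 1L)
    stop(what, " expects samples from a single age group; found: ",
         paste(ag, collapse = ", "), ". Subset the experiment first.")
  ag
}

#' Write a result table as TSV
#'
#' Writes any result data.frame with a deterministic column order, a header
#' line, numeric values at 6 significant digits and `NA` as the single
#' missing-value token. Optional comment lines (prefixed with `#`) carry
#' provenance such as the package version and a configuration hash.
#'
#' @param x data.frame of results.
#' @param path output path.
#' @param comments character vector of provenance lines to prepend (written
#'   as `# ...`); `NULL` for none.
#' @return Invisibly, `path`.
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(x, path, comments = NULL) {
  x <- as.data.frame(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  out <- x
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (j in which(num)) out[[j]] <- .format_num(out[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#'
#' @param path TSV path; `#`-prefixed provenance lines are skipped.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
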