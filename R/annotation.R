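#' Read a transcript annotation table
#'
#' The pipeline's gene-model contract is a plain TSV ("GTF-lite") with columns
#' `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `cds_start` (0-based position of the A of the start codon, or `NA`), and
#' `low_confidence` (TRUE for RIKEN cDNAs / predicted genes, which are
#' deprioritized during observed-TSS deduplication). Coordinates are 0-based
#' half-open. The annotated TSS is the 5' end of the interval on its strand:
#' `start` on `+`, `end - 1` on `-`.
#'
#' @param path TSV file with a header row.
#' @return A `TranscriptAnnotation` data.frame with a derived `tss` column.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  transcript_annotation(df)
}

#' Construct / validate a transcript annotation table
#'
#' @param df data.frame with the columns documented in [read_annotation()].
#' @return A validated `TranscriptAnnotation` data.frame (with `tss` filled).
#' @export
transcript_annotation <- function(df) {
  required <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(df$cds_start)) df$cds_start <- NA_integer_
  if (is.null(df$low_confidence)) df$low_confidence <- FALSE
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$cds_start <- as.integer(df$cds_start)
  df$low_confidence <- as.logical(df$low_confidence)
  stopifnot(all(df$start < df$end), all(df$strand %in% c("+", "-")))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  ok <- is.na(df$cds_start) |
    (df$cds_start >= df$start & df$cds_start < df$end)
  if (!all(ok)) stop("cds_start outside transcript interval")
  class(df) <- c("TranscriptAnnotation", "data.frame")
  df
}

#' Write a transcript annotation table
#' @param anno a `TranscriptAnnotation` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(anno, path) {
  cols <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
            "cds_start", "low_confidence")
  utils::write.table(as.data.frame(anno)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file (e.g. binding peaks)
#' @param path BED3+ file, 0-based half-open.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_peaks_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
             end = as.integer(raw[[3]]), stringsAsFactors = FALSE)
}
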