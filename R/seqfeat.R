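# Promoter sequence features: CCAAT-box counting, initiator dinucleotide
# extraction, conservation-profile aggregation.

#' Read a genome FASTA into a named list of sequences
#' @param path FASTA file.
#' @return Named list of upper-case chromosome sequences (character).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.list(toupper(as.character(ss)))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named list of sequences as FASTA
#' @param genome named list of chromosome sequences (character).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Count CCAAT boxes on both strands
#'
#' Counts occurrences of `CCAAT` plus `ATTGG` (the reverse-strand CCAAT) in
#' the given sequence; overlapping matches count. The recognition element is
#' bound in either orientation, so
#' `count_ccaat(s) == count_ccaat(reverse_complement(s))`.
#'
#' @param sequence character vector of DNA sequences.
#' @return Integer count(s).
#' @export
count_ccaat <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    n <- 0L
    for (motif in c("(?=CCAAT)", "(?=ATTGG)")) {
      hits <- gregexpr(motif, s, perl = TRUE)[[1]]
      if (hits[1] != -1L) n <- n + length(hits)
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

#' Initiator dinucleotide at a TSS
#'
#' Extracts the sense-strand 2-mer spanning offsets -1 and 0 of the TSS (the
#' base preceding initiation, then the first transcribed base) and flags the
#' pyrimidine-purine (YR) initiator configuration: first base C/T, second
#' base A/G.
#'
#' @param genome named list of chromosome sequences.
#' @param chrom chromosome.
#' @param tss 0-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @return List with `dinucleotide` and logical `yr`.
#' @export
initiator_at <- function(genome, chrom, tss, strand) {
  dinuc <- region_sequence(genome, chrom,
                           if (strand == "+") tss - 1L else tss,
                           if (strand == "+") tss + 1L else tss + 2L,
                           strand)
  first <- substr(dinuc, 1L, 1L)
  second <- substr(dinuc, 2L, 2L)
  list(dinucleotide = dinuc,
       yr = first %in% c("C", "T") && second %in% c("A", "G"))
}

#' Conservation profile around anchors
#'
#' Pure aggregation of an externally supplied per-base score track (e.g.
#' PhyloP read from bedGraph with `default = NA`): strand-oriented per-offset
#' means across anchors, with missing bases excluded from each mean, plus the
#' per-gene window mean.
#'
#' @param track a score `SignalTrack` (`NA` default for missing bases).
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param window inclusive offset bounds (default `c(-1000, 1000)`).
#' @return List with `offsets`, `profile` (per-offset mean), `matrix` and
#'   `gene_mean` (row means, missing bases excluded).
#' @export
conservation_profile <- function(track, anchors, window = c(-1000L, 1000L)) {
  prof <- occupancy_profile(track, anchors, window)
  prof$gene_mean <- rowMeans(prof$matrix, na.rm = TRUE)
  prof
}

#' Promoter feature table
#'
#' Per-gene CCAAT count in the 1-kb region upstream of the canonical TSS
#' (offsets -1000..-1, both strands), the canonical initiator dinucleotide
#' and its YR flag, and — where an ectopic call exists — the ectopic
#' initiator.
#'
#' @param genome named list of chromosome sequences.
#' @param calls `ObservedTssCall` data.frame.
#' @param ectopic `EctopicTssCall` data.frame (may be empty).
#' @return A `PromoterFeatureRow` data.frame.
#' @export
promoter_features <- function(genome, calls, ectopic) {
  n <- nrow(calls)
  ccaat <- integer(n)
  dinuc <- character(n)
  yr <- logical(n)
  e_dinuc <- rep(NA_character_, n)
  e_yr <- rep(NA, n)
  for (i in seq_len(n)) {
    tss <- calls$observed[i]
    strand <- calls$strand[i]
    up <- if (strand == "+") {
      region_sequence(genome, calls$chrom[i], max(tss - 1000L, 0L), tss, "+")
    } else {
      region_sequence(genome, calls$chrom[i], tss + 1L, tss + 1001L, "-")
    }
    ccaat[i] <- count_ccaat(up)
    ini <- initiator_at(genome, calls$chrom[i], tss, strand)
    dinuc[i] <- ini$dinucleotide
    yr[i] <- ini$yr
    j <- match(calls$gene_id[i], ectopic$gene_id)
    if (!is.na(j)) {
      ini_e <- initiator_at(genome, calls$chrom[i], ectopic$position[j],
                            strand)
      e_dinuc[i] <- ini_e$dinucleotide
      e_yr[i] <- ini_e$yr
    }
  }
  out <- data.frame(
    gene_id = calls$gene_id,
    ccaat_upstream = ccaat,
    initiator = dinuc,
    initiator_yr = yr,
    ectopic_initiator = e_dinuc,
    ectopic_initiator_yr = e_yr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("PromoterFeatureRow", "data.frame")
  out
}
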