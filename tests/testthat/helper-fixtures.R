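# Small in-code fixture builders shared across test files.

# Track with given values at given 0-based positions on one chromosome.
make_track <- function(pos, val, strand = "+", chrom = "chr1") {
  track_add(signal_track(strand = strand), chrom, pos, val)
}

# A stranded track pair (only one strand populated).
make_pair <- function(pos, val, strand = "+", chrom = "chr1") {
  pair <- list("+" = signal_track("+"), "-" = signal_track("-"))
  pair[[strand]] <- track_add(pair[[strand]], chrom, pos, val)
  pair
}

# One-transcript annotation with the TSS at `tss`.
make_anno <- function(tss = 5000L, strand = "+", chrom = "chr1",
                      gene_len = 2000L, id = "g1", cds_offset = 300L,
                      low_confidence = FALSE) {
  start <- if (strand == "+") tss else tss - gene_len + 1L
  end <- if (strand == "+") tss + gene_len else tss + 1L
  transcript_annotation(data.frame(
    transcript_id = paste0(id, ".1"), gene_id = id, chrom = chrom,
    start = start, end = end, strand = strand,
    cds_start = offset_to_position(cds_offset, tss, strand),
    low_confidence = low_confidence, stringsAsFactors = FALSE))
}

# Uniform Pol II coverage around a TSS so the rescue rule stays silent.
make_polII <- function(tss, level = 10, halfwidth = 1500L, chrom = "chr1") {
  track_add(signal_track("*"), chrom,
            seq.int(max(tss - halfwidth, 0L), tss + halfwidth), level)
}

# A minimal ObservedTssCall row for modules anchored on calls.
make_call <- function(tss = 5000L, strand = "+", chrom = "chr1",
                      gene_id = "g1") {
  structure(data.frame(
    transcript_id = paste0(gene_id, ".1"), gene_id = gene_id, chrom = chrom,
    strand = strand, annotated = tss, observed = tss,
    source = "startseq_primary", reads = 100, distance = 0L,
    low_confidence = FALSE, stringsAsFactors = FALSE),
    class = c("ObservedTssCall", "data.frame"))
}

# Random multi-gene fixture for the observed-TSS oracle comparison: genes on
# both strands with random 5'-end spikes, noise, and heterogeneous Pol II.
random_observed_fixture <- function(n_genes, seed) {
  set.seed(seed)
  rows <- list()
  start5p <- list("+" = signal_track("+"), "-" = signal_track("-"))
  polII <- signal_track("*")
  for (i in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    tss <- 3000L + (i - 1L) * 4000L
    rows[[i]] <- data.frame(
      transcript_id = sprintf("t%02d", i), gene_id = sprintf("g%02d", i),
      chrom = "chr1",
      start = if (strand == "+") tss else tss - 1500L,
      end = if (strand == "+") tss + 1500L else tss + 1L,
      strand = strand, cds_start = NA_integer_,
      low_confidence = FALSE, stringsAsFactors = FALSE)
    # noise plus a handful of candidate peaks at random offsets
    n_noise <- sample(5:30, 1)
    noise_off <- sample(-1000:1000, n_noise)
    noise_val <- sample(0:6, n_noise, replace = TRUE)
    n_peak <- sample(0:3, 1)
    peak_off <- if (n_peak) sample(-1000:1000, n_peak) else integer(0)
    peak_val <- if (n_peak) sample(3:60, n_peak, replace = TRUE) else integer(0)
    off <- c(noise_off, peak_off)
    val <- c(noise_val, peak_val)
    keep <- val > 0
    if (any(keep)) {
      start5p[[strand]] <- track_add(
        start5p[[strand]], "chr1",
        offset_to_position(off[keep], tss, strand), val[keep])
    }
    # Pol II: sometimes depleted away from the annotation to trip the rescue
    pol_level <- sample(c(0, 1, 5), 3, replace = TRUE)
    polII <- track_add(polII, "chr1", seq.int(tss - 1300L, tss - 301L),
                       pol_level[1])
    polII <- track_add(polII, "chr1", seq.int(tss - 300L, tss + 300L),
                       pol_level[2])
    polII <- track_add(polII, "chr1", seq.int(tss + 301L, tss + 1300L),
                       pol_level[3])
  }
  anno <- transcript_annotation(do.call(rbind, rows))
  list(anno = anno, start5p = start5p, polII = polII)
}
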