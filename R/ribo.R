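# Ribo-Seq analysis: P-site inference, triplet-periodicity scoring, upstream
# ATG selection in ectopically transcribed regions, and shifted-region
# translation quantification.

#' P-site track from ribosome footprints
#'
#' Each footprint contributes +1 at its 5' end plus `psite_offset` (12) nt in
#' the direction of transcription: genomic `start + 12` on `+`, genomic
#' `(end - 1) - 12` on `-`. A fixed offset is used for all fragment lengths.
#'
#' @param frags a stranded `FragmentSet` of footprints.
#' @param cfg a [pipeline_config()].
#' @return Named list of `SignalTrack`s, elements `"+"` and `"-"`; their
#'   combined total equals `nrow(frags)`.
#' @export
psite_track <- function(frags, cfg = pipeline_config()) {
  off <- cfg$psite_offset
  out <- list("+" = signal_track("+", "P-sites"),
              "-" = signal_track("-", "P-sites"))
  for (s in c("+", "-")) {
    sub <- frags[frags$strand == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- if (s == "+") sub$start + off else (sub$end - 1L) - off
    for (cn in unique(sub$chrom)) {
      out[[s]] <- track_add(out[[s]], cn, pos[sub$chrom == cn], 1)
    }
  }
  out
}

#' Triplet periodicity of P-sites downstream of an anchor
#'
#' Assigns each P-site in the inclusive offset span `[0, 3*span_codons - 1]`
#' downstream of the anchor (the A of an ATG) to reading frame
#' `offset mod 3`, and tests the frame counts against the uniform (1/3, 1/3,
#' 1/3) law with a chi-square goodness-of-fit test. RNA-Seq-like coverage
#' shows no periodicity (frame-0 fraction near 1/3); translated regions are
#' strongly frame-0 enriched.
#'
#' @param psites named list of P-site `SignalTrack`s (`"+"`/`"-"`).
#' @param chrom,anchor,strand anchor coordinates (A of the start codon).
#' @param span_codons codons scanned downstream (default 60).
#' @return A `PhasingResult` list: `frames` (f0, f1, f2), `total`,
#'   `frame0_fraction`, `chisq`, `p`.
#' @export
phasing <- function(psites, chrom, anchor, strand, span_codons = 60L) {
  v <- track_window(psites[[strand]], chrom, anchor, strand,
                    0L, 3L * span_codons - 1L)
  frames <- as.numeric(rowsum(v, rep_len(0:2, length(v))))
  total <- sum(frames)
  if (total == 0) {
    return(structure(list(frames = frames, total = 0,
                          frame0_fraction = NA_real_,
                          chisq = NA_real_, p = NA_real_),
                     class = "PhasingResult"))
  }
  e <- total / 3
  chisq <- sum((frames - e)^2 / e)
  structure(list(frames = frames, total = total,
                 frame0_fraction = frames[1] / total,
                 chisq = chisq,
                 p = stats::pchisq(chisq, df = 2, lower.tail = FALSE)),
            class = "PhasingResult")
}

#' @export
print.PhasingResult <- function(x, ...) {
  cat(sprintf("PhasingResult: frames %s (n=%g), frame0 %.3f, chisq %.2f, p %.3g\n",
              paste(x$frames, collapse = "/"), x$total,
              x$frame0_fraction, x$chisq, x$p))
  invisible(x)
}

# Sense-strand sequence of the half-open genomic interval [start, end),
# oriented 5'->3' for the given strand.
region_sequence <- function(genome, chrom, start, end, strand) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome not in genome: ", chrom)
  s <- substr(seq, start + 1L, end)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# Genomic coordinates of the shifted region: ectopic TSS up to (but not
# including) `margin` nt upstream of the canonical TSS, strandwise.
shifted_region_bounds <- function(ectopic_pos, canonical_pos, strand,
                                  margin = 25L) {
  if (strand == "+") {
    c(start = ectopic_pos, end = canonical_pos - margin)
  } else {
    c(start = canonical_pos + margin + 1L, end = ectopic_pos + 1L)
  }
}

#' Does the ectopically transcribed region contain a sense-strand ATG?
#'
#' @param region_seq sense-strand sequence of the shifted region (5'->3').
#' @return Logical.
#' @export
has_upstream_atg <- function(region_seq) {
  grepl("ATG", region_seq, fixed = TRUE)
}

#' Select the translated upstream ATG in a shifted region
#'
#' Scans the sense strand of the region between the ectopic and the canonical
#' TSS for ATG triplets and picks the one with the highest P-site coverage in
#' the `atg_window` (60) nt downstream of its A; ties go to the ATG nearest
#' the ectopic TSS.
#'
#' @param genome named list of chromosome sequences (character).
#' @param psites named list of P-site `SignalTrack`s (`"+"`/`"-"`).
#' @param chrom chromosome.
#' @param ectopic_pos,canonical_pos 0-based ectopic and canonical TSS.
#' @param strand `"+"` or `"-"`.
#' @param cfg a [pipeline_config()].
#' @return List with `anchor` (0-based genomic position of the A), `coverage`
#'   (window P-site sum) and `offset_in_region`, or `NULL` when the region
#'   holds no ATG.
#' @export
select_ectopic_atg <- function(genome, psites, chrom, ectopic_pos,
                               canonical_pos, strand,
                               cfg = pipeline_config()) {
  b <- shifted_region_bounds(ectopic_pos, canonical_pos, strand,
                             cfg$ribo_region_margin)
  if (b["end"] <= b["start"]) return(NULL)
  s <- region_sequence(genome, chrom, b["start"], b["end"], strand)
  hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  rel <- as.integer(hits) - 1L  # 0-based offset of the A within the region
  anchors <- if (strand == "+") b["start"] + rel else (b["end"] - 1L) - rel
  cov <- vapply(anchors, function(a) {
    sum(track_window(psites[[strand]], chrom, a, strand,
                     0L, cfg$atg_window - 1L))
  }, numeric(1))
  best <- which(cov == max(cov))[1]  # first hit = nearest the ectopic TSS
  list(anchor = unname(anchors[best]), coverage = unname(cov[best]),
       offset_in_region = unname(rel[best]))
}

#' RPKM of the shifted (or surrogate) promoter-proximal region
#'
#' For a gene with an ectopic call the region runs from the ectopic TSS to
#' `ribo_region_margin` (25) nt upstream of the canonical TSS (strandwise).
#' Genes without promoter-proximal binding use the fixed surrogate region
#' between `control_region_upstream` (115, the median shift distance) and 25
#' nt upstream of their TSS. RPKM = fragments overlapping the region /
#' (region length in kb x mapped reads in millions).
#'
#' @param frags a `FragmentSet` of footprints (one library).
#' @param total_mapped library size used for the per-million factor.
#' @param chrom chromosome.
#' @param canonical_pos 0-based canonical TSS.
#' @param strand `"+"` or `"-"`.
#' @param ectopic_pos 0-based ectopic TSS, or `NULL` to use the surrogate
#'   region.
#' @param cfg a [pipeline_config()].
#' @return List with `start`, `end`, `length`, `count`, `rpkm`.
#' @export
shifted_region_rpkm <- function(frags, total_mapped, chrom, canonical_pos,
                                strand, ectopic_pos = NULL,
                                cfg = pipeline_config()) {
  if (is.null(ectopic_pos)) {
    ectopic_pos <- offset_to_position(-cfg$control_region_upstream,
                                      canonical_pos, strand)
  }
  b <- shifted_region_bounds(ectopic_pos, canonical_pos, strand,
                             cfg$ribo_region_margin)
  len <- unname(b["end"] - b["start"])
  stopifnot(len > 0)
  sel <- frags$chrom == chrom & frags$start < b["end"] & frags$end > b["start"]
  count <- sum(sel)
  list(start = unname(b["start"]), end = unname(b["end"]),
       length = unname(len), count = count,
       rpkm = count / ((len / 1000) * (total_mapped / 1e6)))
}

#' Drop genes dominating the Ribo-Seq library from phasing analyses
#'
#' Removes genes whose cumulative shifted-region signal represents strictly
#' more than `ribo_gene_read_fraction_max` (5%) of the total library;
#' a gene at exactly the threshold is kept.
#'
#' @param region_counts named per-gene read counts in the shifted regions.
#' @param library_total total Ribo-Seq reads in the library.
#' @param cfg a [pipeline_config()].
#' @return Names of the retained genes.
#' @export
filter_dominant_genes <- function(region_counts, library_total,
                                  cfg = pipeline_config()) {
  names(region_counts)[region_counts / library_total <=
                         cfg$ribo_gene_read_fraction_max]
}

#' Cumulative P-site coverage anchored on selected start codons
#'
#' Sums strand-oriented coverage across anchors (the A of each selected ATG)
#' per offset; minus-strand anchors are mirrored so positive offsets run
#' downstream.
#'
#' @param psites named list of P-site `SignalTrack`s (`"+"`/`"-"`).
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param window inclusive offset bounds (default `c(-30, 180)`).
#' @return List with `offsets` and `coverage` (summed across anchors).
#' @export
cumulative_coverage <- function(psites, anchors, window = c(-30L, 180L)) {
  offs <- seq.int(window[1], window[2])
  acc <- numeric(length(offs))
  for (i in seq_len(nrow(anchors))) {
    acc <- acc + track_window(psites[[anchors$strand[i]]], anchors$chrom[i],
                              anchors$pos[i], anchors$strand[i],
                              window[1], window[2])
  }
  list(offsets = offs, coverage = acc)
}
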