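# Observed (canonical) TSS resolution from control Start-Seq 5' end counts.
#
# Tie rules used by every argmax in this file: positions with equal counts are
# broken toward the annotated TSS (smallest |offset|), and a remaining tie
# toward the upstream-most position, so calls never depend on scan order.

pick_argmax_offset <- function(vals, offsets) {
  mx <- max(vals)
  cand <- offsets[vals == mx]
  cand <- cand[abs(cand) == min(abs(cand))]
  min(cand)
}

#' Call the observed TSS for each annotated transcript
#'
#' For every transcript the caller:
#' \enumerate{
#'   \item finds candidate A, the position with the highest 5'-end read count
#'     within `tss_search_radius` nt of the annotated TSS, and candidate B,
#'     the highest-count position inside the `density_window`-nt window of
#'     highest summed read density in that range, and selects whichever lies
#'     closer to the annotation (A on ties);
#'   \item compares Pol II signal in the 501-nt window centered on the
#'     selected locus with the same window about the annotated TSS; if the
#'     ratio is below `polII_ratio_threshold` (2:3), re-selects the
#'     highest-count position within `polII_window` (250) nt of the
#'     annotation (source `polII_rescued`);
#'   \item if fewer than `min_tss_reads` (5) reads map to the selected locus,
#'     maintains the annotated TSS (source `annotation_lowreads`).
#' }
#' Transcripts whose chromosome is absent from the 5'-end track keep the
#' annotation with source `annotation_kept` and a warning.
#'
#' @param anno a `TranscriptAnnotation` data.frame (see [read_annotation()]).
#' @param start5p named list of `SignalTrack`s, elements `"+"` and `"-"`, of
#'   combined raw control 5'-end counts.
#' @param polII unstranded `SignalTrack` of Pol II ChIP coverage.
#' @param cfg a [pipeline_config()].
#' @return An `ObservedTssCall` data.frame with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `annotated`, `observed`, `source`, `reads`
#'   (5'-end count at the call), `distance` (signed strandwise offset,
#'   annotated to observed), and `low_confidence`.
#' @export
call_observed_tss <- function(anno, start5p, polII, cfg = pipeline_config()) {
  stopifnot(inherits(anno, "TranscriptAnnotation"))
  n <- nrow(anno)
  observed <- integer(n)
  source <- character(n)
  reads <- numeric(n)
  R <- cfg$tss_search_radius
  W <- cfg$density_window
  P <- cfg$polII_window
  missing_chroms <- character(0)

  for (i in seq_len(n)) {
    chrom <- anno$chrom[i]
    strand <- anno$strand[i]
    tss <- anno$tss[i]
    tr <- start5p[[strand]]
    if (is.null(tr) || !track_has_chrom(tr, chrom)) {
      observed[i] <- tss
      source[i] <- "annotation_kept"
      reads[i] <- 0
      missing_chroms <- union(missing_chroms, chrom)
      next
    }
    offsets <- seq.int(-R, R)
    counts <- track_window(tr, chrom, tss, strand, -R, R)

    off_a <- pick_argmax_offset(counts, offsets)

    # 200-nt sliding window of highest summed density, step 1 nt;
    # ties -> window whose midpoint is closest to the annotation, then the
    # upstream-most window.
    cs <- cumsum(c(0, counts))
    wsum <- cs[(W + 1):length(cs)] - cs[1:(length(cs) - W)]
    wstart <- offsets[seq_along(wsum)]
    wmid <- wstart + (W - 1) / 2
    best <- wsum == max(wsum)
    best <- best & abs(wmid) == min(abs(wmid)[best])
    k <- which(best)[1]
    in_win <- seq.int(k, k + W - 1L)
    off_b <- pick_argmax_offset(counts[in_win], offsets[in_win])

    sel <- if (abs(off_a) <= abs(off_b)) off_a else off_b
    src <- if (abs(off_a) <= abs(off_b)) "startseq_primary" else
      "startseq_density"

    # Pol II comparison: summed coverage in the 501-nt genomic windows
    # centered on the selected locus and on the annotated TSS.
    sel_pos <- offset_to_position(sel, tss, strand)
    pol_sel <- sum(track_slice(polII, chrom, sel_pos - P, sel_pos + P + 1L))
    pol_ann <- sum(track_slice(polII, chrom, tss - P, tss + P + 1L))
    if (pol_sel < cfg$polII_ratio_threshold * pol_ann) {
      idx <- which(offsets >= -P & offsets <= P)
      sel <- pick_argmax_offset(counts[idx], offsets[idx])
      src <- "polII_rescued"
    }

    sel_reads <- counts[match(sel, offsets)]
    if (sel_reads < cfg$min_tss_reads) {
      sel <- 0L
      src <- "annotation_lowreads"
      sel_reads <- counts[match(0L, offsets)]
    }
    observed[i] <- offset_to_position(sel, tss, strand)
    source[i] <- src
    reads[i] <- sel_reads
  }
  if (length(missing_chroms)) {
    warning("no 5'-end signal for chromosome(s) ",
            paste(missing_chroms, collapse = ", "),
            "; annotation kept for their transcripts")
  }
  calls <- data.frame(
    transcript_id = anno$transcript_id,
    gene_id = anno$gene_id,
    chrom = anno$chrom,
    strand = anno$strand,
    annotated = anno$tss,
    observed = observed,
    source = source,
    reads = reads,
    distance = to_offset(observed, anno$tss, anno$strand),
    low_confidence = anno$low_confidence,
    stringsAsFactors = FALSE
  )
  class(calls) <- c("ObservedTssCall", "data.frame")
  calls
}

#' Reduce observed TSS calls to single representatives
#'
#' Two-stage reduction: (a) transcripts with identical observed TSS (same
#' chromosome and strand) keep the single call with the shortest
#' annotated-to-observed distance; (b) the survivors are clustered by
#' single-linkage within `dedup_group_radius` nt (same strand); within each
#' cluster, low-confidence annotations (RIKEN cDNAs, predicted genes) and
#' calls that fell back to the annotation for lack of reads are dropped
#' first (unless that would empty the cluster), then the call with the
#' shortest distance is kept. Idempotent once no two surviving same-strand
#' calls lie within the radius.
#'
#' @param calls an `ObservedTssCall` data.frame.
#' @param cfg a [pipeline_config()].
#' @return The reduced `ObservedTssCall` data.frame.
#' @export
deduplicate_calls <- function(calls, cfg = pipeline_config()) {
  if (nrow(calls) == 0) return(calls)
  # (a) identical observed positions
  key <- paste(calls$chrom, calls$strand, calls$observed)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), key), function(idx) {
    d <- abs(calls$distance[idx])
    idx[which.min(d)]
  }), use.names = FALSE)
  calls <- calls[sort(keep), , drop = FALSE]

  # (b) single-linkage clusters within the radius, per chrom + strand
  radius <- cfg$dedup_group_radius
  survivors <- integer(0)
  for (grp in split(seq_len(nrow(calls)),
                    paste(calls$chrom, calls$strand))) {
    ord <- grp[order(calls$observed[grp])]
    pos <- calls$observed[ord]
    breaks <- c(0L, which(diff(pos) > radius), length(ord))
    for (j in seq_len(length(breaks) - 1L)) {
      cl <- ord[(breaks[j] + 1L):breaks[j + 1L]]
      good <- cl[!calls$low_confidence[cl] &
                   calls$source[cl] != "annotation_lowreads"]
      if (length(good) == 0L) good <- cl
      d <- abs(calls$distance[good])
      survivors <- c(survivors, good[which.min(d)])
    }
  }
  calls[sort(survivors), , drop = FALSE]
}

#' Classify promoters as factor-bound by peak intersection
#'
#' A call is bound when a binding peak intersects the inclusive
#' `bound_window` (default -900..+100 nt) around its observed TSS, oriented
#' by strand. A peak touching exactly the boundary base (e.g. offset +100)
#' counts as bound.
#'
#' @param calls an `ObservedTssCall` data.frame.
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`;
#'   0-based half-open), e.g. from [read_peaks_bed()].
#' @param cfg a [pipeline_config()].
#' @return Logical vector parallel to `calls`.
#' @export
classify_nfy_bound <- function(calls, peaks, cfg = pipeline_config()) {
  lo <- cfg$bound_window[1]
  hi <- cfg$bound_window[2]
  win_start <- ifelse(calls$strand == "+", calls$observed + lo,
                      calls$observed - hi)
  win_end <- ifelse(calls$strand == "+", calls$observed + hi + 1L,
                    calls$observed - lo + 1L)
  vapply(seq_len(nrow(calls)), function(i) {
    p <- peaks[peaks$chrom == calls$chrom[i], , drop = FALSE]
    any(p$start < win_end[i] & p$end > win_start[i])
  }, logical(1))
}
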