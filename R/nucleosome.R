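# MNase-Seq nucleosome occupancy profiling and TSS-encroachment calls.

#' Length-filter and deduplicate MNase fragments
#'
#' Keeps fragments of mononucleosomal length (inclusive bounds
#' `mnase_len_min`..`mnase_len_max`, default 120..180 nt — fragments shorter
#' than 120 or larger than 180 are dropped) and removes duplicate fragments.
#' The two steps commute; both are idempotent.
#'
#' @param frags a `FragmentSet`.
#' @param cfg a [pipeline_config()].
#' @return The filtered, deduplicated `FragmentSet`.
#' @export
filter_fragments <- function(frags, cfg = pipeline_config()) {
  dedup_fragments(
    filter_fragment_lengths(frags, cfg$mnase_len_min, cfg$mnase_len_max)
  )
}

#' Metagene occupancy profile around anchors
#'
#' Strand-oriented per-offset aggregation of a signal track over a set of
#' anchors: each anchor contributes its inclusive offset window, mirrored for
#' minus-strand anchors so that positive offsets always run downstream.
#' Missing values (`NA`, as in score tracks) are dropped from the means.
#'
#' @param track a `SignalTrack` (e.g. normalized fragment centers).
#' @param anchors data.frame with `chrom`, `pos` (0-based anchor base) and
#'   `strand` columns; row order is preserved in the matrix.
#' @param window inclusive offset bounds, e.g. `c(-1000, 1000)`.
#' @return List with `offsets`, `profile` (per-offset mean across anchors) and
#'   `matrix` (anchors x offsets).
#' @export
occupancy_profile <- function(track, anchors, window = c(-1000L, 1000L)) {
  offs <- seq.int(window[1], window[2])
  if (nrow(anchors) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(offs))
  } else {
    m <- t(vapply(seq_len(nrow(anchors)), function(i) {
      track_window(track, anchors$chrom[i], anchors$pos[i],
                   anchors$strand[i], window[1], window[2])
    }, numeric(length(offs))))
    rownames(m) <- rownames(anchors)
  }
  colnames(m) <- offs
  list(offsets = offs, profile = colMeans(m, na.rm = TRUE), matrix = m)
}

#' TSS-window nucleosome occupancy change
#'
#' Compares knockdown against control occupancy (per-10M fragment-center
#' sums) over a window around each observed TSS (default the core -25..+24
#' region whose occlusion defines encroachment). The fold change is
#' `(KD + c) / (control + c)` with a pseudocount `c` of one normalized unit,
#' and a promoter is classified as encroached when the fold change reaches
#' `mnase_fc_threshold` (1.5).
#'
#' @param control,kd unstranded normalized fragment-center `SignalTrack`s.
#' @param calls `ObservedTssCall` data.frame (anchors).
#' @param cfg a [pipeline_config()]; `mnase_window` sets the window.
#' @param pseudocount added to both window sums (default 1).
#' @return An `OccupancyChange` data.frame with `gene_id`, `control_occ`,
#'   `kd_occ`, `log2fc`, `fold_change`, `encroached`.
#' @export
tss_occupancy_change <- function(control, kd, calls,
                                 cfg = pipeline_config(), pseudocount = 1) {
  lo <- cfg$mnase_window[1]
  hi <- cfg$mnase_window[2]
  occ <- function(track, i) {
    sum(track_window(track, calls$chrom[i], calls$observed[i],
                     calls$strand[i], lo, hi))
  }
  ctl <- vapply(seq_len(nrow(calls)), function(i) occ(control, i), numeric(1))
  kdv <- vapply(seq_len(nrow(calls)), function(i) occ(kd, i), numeric(1))
  fc <- (kdv + pseudocount) / (ctl + pseudocount)
  out <- data.frame(
    gene_id = calls$gene_id,
    control_occ = ctl,
    kd_occ = kdv,
    fold_change = fc,
    log2fc = log2(fc),
    encroached = fc >= cfg$mnase_fc_threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("OccupancyChange", "data.frame")
  out
}
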