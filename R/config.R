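#' Pipeline configuration
#'
#' Collects every fixed constant the pipeline stages share. All window bounds
#' are strand-relative offsets in nucleotides around an anchor (usually the
#' observed TSS): offset 0 is the anchor base, positive offsets run downstream
#' in the direction of transcription, and quoted inclusive windows such as
#' \code{-900..+100} are realized as inclusive offset ranges. Internal
#' coordinates are 0-based, half-open throughout (BED/bedGraph convention).
#'
#' @param tss_search_radius nt searched around an annotated TSS when resolving
#'   the observed TSS (default 1000).
#' @param density_window width (nt) of the sliding window used to find the
#'   region of highest 5'-end read density (default 200).
#' @param polII_ratio_threshold Pol II signal ratio (selected vs annotated
#'   501-nt window) below which the call is re-selected near the annotation
#'   (default 2/3).
#' @param polII_window half-width (nt) of the Pol II comparison window and of
#'   the rescue re-selection range (default 250; windows are 501 nt).
#' @param min_tss_reads minimum 5'-end reads at a called position; below this
#'   the annotated TSS is maintained (default 5).
#' @param dedup_group_radius nt radius for clustering observed TSS calls when
#'   reducing to a single representative (default 200).
#' @param bound_window inclusive offset range around the observed TSS that a
#'   binding peak must intersect for a promoter to count as factor-bound
#'   (default c(-900, 100)).
#' @param bin_region inclusive offset range tiled with bins for the ectopic
#'   initiation test (default c(-995, 995)).
#' @param bin_width bin width in nt (default 10).
#' @param core_exclusion inclusive offset range around the observed TSS whose
#'   bins are never tested (default c(-25, 24)); ectopic calls are thereby
#'   guaranteed to lie outside +/-25 nt of the canonical TSS.
#' @param padj_threshold BH-adjusted p-value cutoff for significant bins
#'   (default 0.1).
#' @param shift_min_distance nt; minimum |offset| an ectopic call can have,
#'   implied by \code{core_exclusion} (default 25).
#' @param mnase_len_min,mnase_len_max inclusive MNase fragment length bounds in
#'   nt (defaults 120 and 180).
#' @param mnase_fc_threshold fold-change in TSS-window nucleosome occupancy at
#'   or above which a promoter is classified as encroached (default 1.5).
#' @param mnase_window inclusive offset window over which TSS occupancy change
#'   is computed (default the core region, c(-25, 24)).
#' @param psite_offset nt added to a ribosome footprint 5' end to locate the
#'   P-site (default 12).
#' @param atg_window nt downstream of an ATG's A over which P-site coverage is
#'   summed when choosing the used upstream start codon (default 60).
#' @param ribo_gene_read_fraction_max genes whose shifted-region signal exceeds
#'   this fraction of the library are dropped from phasing (default 0.05,
#'   strict inequality).
#' @param control_region_upstream nt; upstream bound of the surrogate region
#'   used for genes without promoter-proximal binding (default 115, the median
#'   shift distance).
#' @param ribo_region_margin nt; the shifted region ends this far upstream of
#'   the canonical TSS (default 25).
#' @param sliding_window nt window for the maximum read-count difference
#'   statistic (default 10).
#' @param norm_denominator read count the per-depth normalization scales to
#'   (default 1e7, i.e. per ten million).
#'
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(tss_search_radius = 1000L,
                            density_window = 200L,
                            polII_ratio_threshold = 2 / 3,
                            polII_window = 250L,
                            min_tss_reads = 5,
                            dedup_group_radius = 200L,
                            bound_window = c(-900L, 100L),
                            bin_region = c(-995L, 995L),
                            bin_width = 10L,
                            core_exclusion = c(-25L, 24L),
                            padj_threshold = 0.1,
                            shift_min_distance = 25L,
                            mnase_len_min = 120L,
                            mnase_len_max = 180L,
                            mnase_fc_threshold = 1.5,
                            mnase_window = c(-25L, 24L),
                            psite_offset = 12L,
                            atg_window = 60L,
                            ribo_gene_read_fraction_max = 0.05,
                            control_region_upstream = 115L,
                            ribo_region_margin = 25L,
                            sliding_window = 10L,
                            norm_denominator = 1e7) {
  cfg <- list(
    tss_search_radius = as.integer(tss_search_radius),
    density_window = as.integer(density_window),
    polII_ratio_threshold = polII_ratio_threshold,
    polII_window = as.integer(polII_window),
    min_tss_reads = min_tss_reads,
    dedup_group_radius = as.integer(dedup_group_radius),
    bound_window = as.integer(bound_window),
    bin_region = as.integer(bin_region),
    bin_width = as.integer(bin_width),
    core_exclusion = as.integer(core_exclusion),
    padj_threshold = padj_threshold,
    shift_min_distance = as.integer(shift_min_distance),
    mnase_len_min = as.integer(mnase_len_min),
    mnase_len_max = as.integer(mnase_len_max),
    mnase_fc_threshold = mnase_fc_threshold,
    mnase_window = as.integer(mnase_window),
    psite_offset = as.integer(psite_offset),
    atg_window = as.integer(atg_window),
    ribo_gene_read_fraction_max = ribo_gene_read_fraction_max,
    control_region_upstream = as.integer(control_region_upstream),
    ribo_region_margin = as.integer(ribo_region_margin),
    sliding_window = as.integer(sliding_window),
    norm_denominator = norm_denominator
  )
  class(cfg) <- c("PipelineConfig", "list")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$tss_search_radius > 0,
    cfg$density_window > 0,
    cfg$bin_width > 0,
    length(cfg$bin_region) == 2L, cfg$bin_region[1] < cfg$bin_region[2],
    length(cfg$core_exclusion) == 2L,
    cfg$core_exclusion[1] <= cfg$core_exclusion[2],
    length(cfg$bound_window) == 2L, cfg$bound_window[1] <= cfg$bound_window[2],
    cfg$mnase_len_min <= cfg$mnase_len_max,
    cfg$norm_denominator > 0
  )
  # the tested region must contain the untested core
  if (cfg$core_exclusion[1] < cfg$bin_region[1] ||
      cfg$core_exclusion[2] > cfg$bin_region[2]) {
    stop("core_exclusion must lie within bin_region")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' everything else keeps its default. The fully resolved configuration is
#' reported via `message()` so each run logs the constants it used.
#'
#' @param path YAML file of key: value pairs (keys as in [pipeline_config()]).
#' @param quiet suppress the resolved-config log message.
#' @return A `PipelineConfig` list.
#' @export
read_pipeline_config <- function(path, quiet = FALSE) {
  user <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(pipeline_config, user)
  if (!quiet) log_config(cfg)
  cfg
}

log_config <- function(cfg) {
  msg <- paste0(names(cfg), " = ",
                vapply(cfg, function(x) paste(format(x), collapse = ".."),
                       character(1)),
                collapse = "; ")
  message("resolved config: ", msg)
}

#' Strand-relative offset between genomic positions
#'
#' Converts a genomic position into a signed offset relative to an anchor,
#' following the anchor's strand: offsets are positive downstream of the
#' anchor (to the right on `+`, to the left on `-`) and 0 at the anchor base.
#'
#' @param pos,anchor 0-based genomic positions (vectors recycle).
#' @param strand `"+"` or `"-"` (anchor strand).
#' @param chrom,anchor_chrom optional chromosome names; if both are given they
#'   must match.
#' @return Integer offset(s).
#' @export
to_offset <- function(pos, anchor, strand, chrom = NULL, anchor_chrom = NULL) {
  if (!is.null(chrom) && !is.null(anchor_chrom) &&
      any(chrom != anchor_chrom)) {
    stop("position and anchor lie on different chromosomes")
  }
  stopifnot(all(strand %in% c("+", "-")))
  strand <- rep_len(strand, max(length(pos), length(anchor), length(strand)))
  ifelse(strand == "+", pos - anchor, anchor - pos)
}

#' Inverse of [to_offset()]: genomic position at a strand-relative offset
#'
#' @param offset signed offset(s) in nt.
#' @param anchor 0-based anchor position(s).
#' @param strand `"+"` or `"-"`.
#' @return 0-based genomic position(s).
#' @export
offset_to_position <- function(offset, anchor, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  strand <- rep_len(strand,
                    max(length(offset), length(anchor), length(strand)))
  ifelse(strand == "+", anchor + offset, anchor - offset)
}
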