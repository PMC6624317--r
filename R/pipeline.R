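# End-to-end orchestration: from a directory of standard-format inputs to a
# report directory of TSV tables. Deterministic given the inputs (no stage
# uses random numbers), so reruns produce byte-identical reports.

read_sample_sheet <- function(dir) {
  utils::read.table(file.path(dir, "samples.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

read_startseq_tracks <- function(dir, samples) {
  out <- lapply(samples, function(s) {
    list("+" = read_bedgraph(file.path(dir, paste0("startseq_", s,
                                                   "_plus.bedgraph")),
                             strand = "+"),
         "-" = read_bedgraph(file.path(dir, paste0("startseq_", s,
                                                   "_minus.bedgraph")),
                             strand = "-"))
  })
  names(out) <- samples
  out
}

sum_track_pairs <- function(pairs) {
  list("+" = track_scale(mean_replicate_track(lapply(pairs, `[[`, "+")),
                         length(pairs)),
       "-" = track_scale(mean_replicate_track(lapply(pairs, `[[`, "-")),
                         length(pairs)))
}

# Spike-normalized per-condition mean tracks: each replicate is depth
# normalized (per ten million), divided by its spike regression factor, and
# replicates are averaged at single-nucleotide resolution.
condition_mean_tracks <- function(tracks, totals, factors, samples, cfg) {
  norm <- lapply(samples, function(s) {
    lapply(tracks[[s]], function(t) {
      t <- normalize_per_ten_million(t, totals[s], cfg$norm_denominator)
      track_scale(t, 1 / factors[s], norm = "spike")
    })
  })
  list("+" = mean_replicate_track(lapply(norm, `[[`, "+")),
       "-" = mean_replicate_track(lapply(norm, `[[`, "-")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline on a directory of standard-format inputs
#'
#' Expects the file layout written by [simulate_dataset()] (which is also the
#' contract for real data prepared externally): annotation, per-sample
#' strand-specific Start-Seq 5'-end bedGraphs, spike-in table, sample sheet,
#' Pol II coverage bedGraph, binding peaks BED, per-condition MNase and
#' Ribo-Seq fragment BEDs, an RNA-Seq-like control BED, and a genome FASTA.
#'
#' Stages: observed-TSS calling and deduplication; promoter binding
#' classification; spike regression factors and median-of-ratios size
#' factors; binned negative-binomial ectopic-TSS calling; shift summary;
#' MNase fragment filtering, occupancy change and encroachment fractions;
#' Ribo-Seq P-site phasing at canonical and selected ectopic start codons,
#' shifted-region RPKM; promoter sequence features; and metagene log2
#' fold-change matrices (pseudocount 0.5 normalized units on both numerator
#' and denominator).
#'
#' @param input_dir directory of inputs.
#' @param out_dir report directory (created; overwritten files replaced).
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list of the main in-memory results (`observed`,
#'   `spike`, `size_factors`, `ectopic`, `shift`, `occupancy`, `ribo_regions`,
#'   `phasing`, `features`, `summary`).
#' @export
run_all <- function(input_dir, out_dir, cfg = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anno <- read_annotation(file.path(input_dir, "annotation.tsv"))
  sheet <- read_sample_sheet(input_dir)
  samples <- sheet$sample
  condition <- sheet$condition
  totals <- stats::setNames(sheet$total_mapped, samples)
  ctl_samples <- samples[condition == "ctl"]
  kd_samples <- samples[condition == "kd"]
  tracks <- read_startseq_tracks(input_dir, samples)
  polII <- read_bedgraph(file.path(input_dir, "polii.bedgraph"))
  genome <- read_genome_fasta(file.path(input_dir, "genome.fa"))

  # --- observed TSSs -------------------------------------------------------
  combined_ctl <- sum_track_pairs(tracks[ctl_samples])
  observed <- call_observed_tss(anno, combined_ctl, polII, cfg)
  observed <- deduplicate_calls(observed, cfg)
  peaks <- read_peaks_bed(file.path(input_dir, "nfy_peaks.bed"))
  observed$bound <- classify_nfy_bound(observed, peaks, cfg)
  write_tsv(observed, file.path(out_dir, "observed_tss.tsv"))

  # --- spike normalization -------------------------------------------------
  spikes <- read_spike_table(file.path(input_dir, "spikes.tsv"))
  spike <- spike_factors(spikes, totals, ref = "auto", cfg$norm_denominator)
  size_factors <- size_factors_from_spikes(spikes)
  write_tsv(data.frame(sample = samples,
                       regression_factor = unname(spike$factors[samples]),
                       size_factor = unname(size_factors[samples])),
            file.path(out_dir, "normalization_factors.tsv"))

  # --- ectopic TSS calling -------------------------------------------------
  ect <- call_ectopic_tss(observed, tracks, size_factors, condition,
                          kd_level = "kd", cfg = cfg)
  write_tsv(ect$bins, file.path(out_dir, "bin_stats.tsv"))
  write_tsv(ect$calls, file.path(out_dir, "ectopic_tss.tsv"))
  shift <- shift_summary(ect$calls)
  shifted_ids <- ect$calls$gene_id

  # --- condition mean tracks and metagene matrices -------------------------
  ctl_mean <- condition_mean_tracks(tracks, totals, spike$factors,
                                    ctl_samples, cfg)
  kd_mean <- condition_mean_tracks(tracks, totals, spike$factors,
                                   kd_samples, cfg)
  anchors <- data.frame(chrom = observed$chrom, pos = observed$observed,
                        strand = observed$strand,
                        row.names = observed$gene_id)
  win <- c(-cfg$tss_search_radius, cfg$tss_search_radius)
  prof_ctl <- stranded_profile(ctl_mean, anchors, win)
  prof_kd <- stranded_profile(kd_mean, anchors, win)
  lfc <- log2((prof_kd$matrix + 0.5) / (prof_ctl$matrix + 0.5))
  utils::write.table(
    data.frame(offset = prof_ctl$offsets,
               mean_log2fc_all = colMeans(lfc),
               mean_log2fc_shifted = colMeans(
                 lfc[rownames(lfc) %in% shifted_ids, , drop = FALSE]),
               mean_log2fc_bound = colMeans(
                 lfc[observed$bound, , drop = FALSE])),
    file.path(out_dir, "startseq_metagene_log2fc.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- upstream sliding-window differences, binding-strength groups --------
  maxdiff <- vapply(seq_len(nrow(observed)), function(i) {
    sliding_max_difference(observed[i, ], ctl_mean, kd_mean, cfg = cfg)
  }, numeric(1))
  chip_counts <- vapply(seq_len(nrow(observed)), function(i) {
    sum(track_window(polII, observed$chrom[i], observed$observed[i],
                     observed$strand[i], cfg$bound_window[1],
                     cfg$bound_window[2]))
  }, numeric(1))
  write_tsv(data.frame(gene_id = observed$gene_id,
                       max_window_diff = maxdiff,
                       chip_group = chip_strength_bins(chip_counts)),
            file.path(out_dir, "upstream_differences.tsv"))

  # --- MNase encroachment --------------------------------------------------
  occ <- mnase_occupancy(input_dir, observed, cfg)
  write_tsv(occ$table, file.path(out_dir, "occupancy_change.tsv"))
  enc <- occ$table$encroached
  sh <- observed$gene_id %in% shifted_ids
  encroach_summary <- data.frame(
    group = c("bound_shifted", "bound_nonshifted"),
    n = c(sum(observed$bound & sh), sum(observed$bound & !sh)),
    frac_encroached = c(mean(enc[observed$bound & sh]),
                        mean(enc[observed$bound & !sh])))
  write_tsv(encroach_summary, file.path(out_dir, "encroachment_summary.tsv"))

  # --- Ribo-Seq ------------------------------------------------------------
  ribo <- ribo_stage(input_dir, genome, anno, observed, ect$calls, cfg)
  write_tsv(ribo$regions, file.path(out_dir, "ribo_regions.tsv"))
  write_tsv(ribo$phasing, file.path(out_dir, "phasing_summary.tsv"))
  write_tsv(ribo$atg, file.path(out_dir, "ectopic_atg_phasing.tsv"))

  # --- sequence features ---------------------------------------------------
  features <- promoter_features(genome, observed, ect$calls)
  write_tsv(features, file.path(out_dir, "promoter_features.tsv"))

  # --- top-level summary ---------------------------------------------------
  summary_df <- data.frame(
    metric = c("n_observed_tss", "n_bound", "n_ectopic_calls",
               "median_shift_distance", "upstream_fraction",
               "frac_encroached_bound_shifted",
               "frac_encroached_bound_nonshifted",
               "frac_kd_region_rpkm_higher"),
    value = c(nrow(observed), sum(observed$bound), shift$n,
              shift$median_shift, shift$upstream_fraction,
              encroach_summary$frac_encroached[1],
              encroach_summary$frac_encroached[2],
              ribo$frac_kd_higher))
  write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "pipeline_config.yaml"))

  invisible(list(observed = observed, spike = spike,
                 size_factors = size_factors, ectopic = ect, shift = shift,
                 occupancy = occ$table, ribo_regions = ribo$regions,
                 phasing = ribo$phasing, features = features,
                 summary = summary_df))
}

# Oriented metagene profile of a stranded track pair.
stranded_profile <- function(pair, anchors, window) {
  offs <- seq.int(window[1], window[2])
  if (nrow(anchors) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(offs))
  } else {
    m <- t(vapply(seq_len(nrow(anchors)), function(i) {
      track_window(pair[[anchors$strand[i]]], anchors$chrom[i],
                   anchors$pos[i], anchors$strand[i], window[1], window[2])
    }, numeric(length(offs))))
    rownames(m) <- rownames(anchors)
  }
  colnames(m) <- offs
  list(offsets = offs, matrix = m)
}

mnase_occupancy <- function(input_dir, observed, cfg) {
  centers <- lapply(c("ctl", "kd"), function(cond) {
    frags <- read_fragments_bed(file.path(input_dir,
                                          paste0("mnase_", cond, ".bed")))
    frags <- filter_fragments(frags, cfg)
    normalize_per_ten_million(fragment_center_track(frags), nrow(frags),
                              cfg$norm_denominator)
  })
  names(centers) <- c("ctl", "kd")
  list(table = tss_occupancy_change(centers$ctl, centers$kd, observed, cfg),
       centers = centers)
}

ribo_stage <- function(input_dir, genome, anno, observed, ectopic, cfg) {
  frags <- lapply(c("ctl", "kd"), function(cond) {
    read_fragments_bed(file.path(input_dir, paste0("ribo_", cond, ".bed")))
  })
  names(frags) <- c("ctl", "kd")
  psites <- lapply(frags, psite_track, cfg = cfg)
  rna <- read_fragments_bed(file.path(input_dir, "rna_ctl.bed"))
  rna_psites <- psite_track(rna, cfg)

  # canonical-ORF phasing pooled across genes, Ribo vs RNA-Seq-like control
  cds <- anno$cds_start[match(observed$transcript_id, anno$transcript_id)]
  cds_anchor <- function(i) cds[i]
  idx <- match(observed$gene_id, ectopic$gene_id)

  pooled <- function(ps, anchor_fun) {
    f <- c(0, 0, 0)
    for (i in seq_len(nrow(observed))) {
      a <- anchor_fun(i)
      if (is.na(a)) next
      ph <- phasing(ps, observed$chrom[i], a, observed$strand[i])
      f <- f + ph$frames
    }
    total <- sum(f)
    e <- total / 3
    chisq <- sum((f - e)^2 / e)
    list(frames = f, total = total, frame0 = f[1] / max(total, 1),
         p = stats::pchisq(chisq, 2, lower.tail = FALSE))
  }

  # per-gene shifted-region RPKM (surrogate region for unbound genes)
  totals <- vapply(frags, nrow, integer(1))
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    e_pos <- if (!is.na(idx[i])) ectopic$position[idx[i]] else NULL
    if (is.na(idx[i]) && observed$bound[i]) return(NULL)
    # the shifted region is only defined for shifts upstream of the core
    if (!is.na(idx[i]) &&
        ectopic$offset[idx[i]] >= -cfg$ribo_region_margin) {
      return(NULL)
    }
    r <- lapply(c("ctl", "kd"), function(cond) {
      shifted_region_rpkm(frags[[cond]], totals[[cond]], observed$chrom[i],
                          observed$observed[i], observed$strand[i],
                          ectopic_pos = e_pos, cfg = cfg)
    })
    data.frame(gene_id = observed$gene_id[i],
               group = if (!is.na(idx[i])) "shifted" else "unbound",
               region_start = r[[1]]$start, region_end = r[[1]]$end,
               ctl_count = r[[1]]$count, kd_count = r[[2]]$count,
               ctl_rpkm = r[[1]]$rpkm, kd_rpkm = r[[2]]$rpkm,
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(regions)) {
    regions <- data.frame(gene_id = character(), group = character(),
                          region_start = integer(), region_end = integer(),
                          ctl_count = integer(), kd_count = integer(),
                          ctl_rpkm = numeric(), kd_rpkm = numeric(),
                          stringsAsFactors = FALSE)
  }
  shifted_rows <- regions$group == "shifted"
  frac_kd_higher <- if (any(shifted_rows)) {
    mean(regions$kd_rpkm[shifted_rows] > regions$ctl_rpkm[shifted_rows])
  } else NA_real_

  # dominant-gene filter, then phasing at the selected ectopic ATG (KD)
  kept <- filter_dominant_genes(
    stats::setNames(regions$kd_count, regions$gene_id), totals[["kd"]], cfg)
  atg_rows <- lapply(which(shifted_rows), function(k) {
    i <- match(regions$gene_id[k], observed$gene_id)
    if (!(regions$gene_id[k] %in% kept)) return(NULL)
    sel <- select_ectopic_atg(genome, psites$kd, observed$chrom[i],
                              ectopic$position[idx[i]], observed$observed[i],
                              observed$strand[i], cfg)
    if (is.null(sel)) return(NULL)
    ph_kd <- phasing(psites$kd, observed$chrom[i], sel$anchor,
                     observed$strand[i], span_codons = 20L)
    ph_ctl <- phasing(psites$ctl, observed$chrom[i], sel$anchor,
                      observed$strand[i], span_codons = 20L)
    data.frame(gene_id = observed$gene_id[i], atg_pos = sel$anchor,
               atg_coverage = sel$coverage,
               kd_frame0 = ph_kd$frame0_fraction, kd_p = ph_kd$p,
               ctl_frame0 = ph_ctl$frame0_fraction, ctl_p = ph_ctl$p,
               stringsAsFactors = FALSE)
  })
  atg <- do.call(rbind, atg_rows[!vapply(atg_rows, is.null, logical(1))])
  if (is.null(atg)) {
    atg <- data.frame(gene_id = character(), atg_pos = integer(),
                      atg_coverage = numeric(), kd_frame0 = numeric(),
                      kd_p = numeric(), ctl_frame0 = numeric(),
                      ctl_p = numeric(), stringsAsFactors = FALSE)
  }

  canon_ribo <- pooled(psites$kd, cds_anchor)
  canon_rna <- pooled(rna_psites, cds_anchor)
  phasing_df <- data.frame(
    context = c("canonical_ribo_kd", "canonical_rna_ctl"),
    f0 = c(canon_ribo$frames[1], canon_rna$frames[1]),
    f1 = c(canon_ribo$frames[2], canon_rna$frames[2]),
    f2 = c(canon_ribo$frames[3], canon_rna$frames[3]),
    frame0_fraction = c(canon_ribo$frame0, canon_rna$frame0),
    p = c(canon_ribo$p, canon_rna$p))

  list(regions = regions, frac_kd_higher = frac_kd_higher,
       phasing = phasing_df, atg = atg, psites = psites,
       rna_psites = rna_psites)
}
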