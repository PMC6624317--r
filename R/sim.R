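# Synthetic multi-omics generator with full ground truth. One simulate call
# emits a small genome plus Start-Seq, MNase-Seq, Ribo-Seq, Pol II and
# binding-peak files in the pipeline's standard formats, together with the
# planted truth (ectopic offsets, nucleosome gains, upstream-ORF positions,
# library scale factors), so that every downstream stage can be validated by
# parameter recovery.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: two
#' conditions (control and knockdown) with three replicates each, 15 capped
#' spike-in RNAs, negative-binomial 5'-end counts (dispersion 0.05), a
#' canonical TSS peak in both conditions and a knockdown-only ectopic peak at
#' a planted upstream offset, mononucleosomal MNase fragments with a
#' knockdown-only TSS-overlapping nucleosome at planted genes, and Ribo-Seq
#' footprints whose P-sites are 85% frame-0 from the canonical ORF and from
#' planted upstream ORFs. Planted shift distances default to a lognormal law
#' with median exactly 115 nt (sigma 0.3 on the log scale, clipped to
#' 40..500 nt so no shift ever lands in the +/-25 core); a uniform
#' alternative over `shift_range` is available.
#'
#' @param n_genes genes simulated (default 200, split over `n_chrom`
#'   chromosomes at one gene per `locus_size` nt).
#' @param n_chrom chromosomes (default 2).
#' @param locus_size nt of genome per gene (default 6000).
#' @param frac_shifted fraction of genes given a knockdown-only ectopic
#'   initiation site (default 0.3).
#' @param frac_bound_extra fraction of genes that are factor-bound but not
#'   shifted (default 0.2); all shifted genes are bound.
#' @param shift_dist `"lognormal"` (median `shift_median`) or `"uniform"`
#'   (over `shift_range`).
#' @param shift_median,shift_sigma,shift_clip lognormal distance parameters.
#' @param shift_range inclusive offset bounds for the uniform alternative
#'   (default `c(-300, -40)`).
#' @param replicates replicates per condition (default 3).
#' @param scale_factors named per-sample true library scale factors; samples
#'   are `ctl_1..ctl_R, kd_1..kd_R`.
#' @param n_spikes spike-in species (default 15).
#' @param spike_mean geometric-center expected reads per spike at factor 1
#'   (default 300).
#' @param bg_rate background 5'-end mean per base per sample at factor 1
#'   within the simulated promoter span (default 0.5).
#' @param promoter_span inclusive offsets around the TSS carrying background
#'   signal (default `c(-1100, 1100)`).
#' @param canonical_mean expected 5'-end reads at the canonical TSS base per
#'   sample (default 100).
#' @param ectopic_mean expected knockdown 5'-end reads at the planted ectopic
#'   base (default 50, ten times the 10-nt-bin background mass).
#' @param dispersion negative-binomial dispersion of all 5'-end counts
#'   (default 0.05).
#' @param polII_level Pol II coverage over TSS +/- 600 nt (default 10).
#' @param nuc_offsets dyad offsets of the -1 and +1 nucleosomes
#'   (default `c(-250, 130)`).
#' @param frags_per_nuc MNase fragments per nucleosome per condition library
#'   (default 25).
#' @param tss_nuc_frags fragments of the knockdown-only TSS nucleosome at
#'   planted genes (default 50, twice the flanking density).
#' @param nuc_gain_prob_shifted,nuc_gain_prob_bound probability of planting
#'   the TSS nucleosome gain at shifted (0.8) and bound non-shifted (0.3)
#'   genes.
#' @param dyad_jitter_sd positional jitter of fragment centers (default 8).
#' @param mnase_frag_len inclusive sampled fragment length range (default
#'   `c(115, 185)`, straddling the 120..180 filter).
#' @param mnase_bg_frags random background fragments per gene per condition
#'   (default 10).
#' @param mnase_dup_frac fraction of fragments duplicated to exercise
#'   deduplication (default 0.03).
#' @param ribo_frags_per_gene footprints on the canonical ORF per gene per
#'   library (default 150).
#' @param uorf_frags knockdown-only footprints on a planted upstream ORF
#'   (default 120).
#' @param uorf_prob probability a shifted gene carries a translated upstream
#'   ORF (default 0.7).
#' @param frame0_purity fraction of ORF P-sites in frame 0 (default 0.85).
#' @param ribo_frag_len footprint length (default 30).
#' @param rna_frags_per_gene uniform (RNA-Seq-like) control fragments per
#'   gene (default 60).
#' @param seed random seed; fully determines every output byte.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 200L,
                       n_chrom = 2L,
                       locus_size = 6000L,
                       frac_shifted = 0.3,
                       frac_bound_extra = 0.2,
                       shift_dist = c("lognormal", "uniform"),
                       shift_median = 115,
                       shift_sigma = 0.3,
                       shift_clip = c(40L, 500L),
                       shift_range = c(-300L, -40L),
                       replicates = 3L,
                       scale_factors = NULL,
                       n_spikes = 15L,
                       spike_mean = 300,
                       bg_rate = 0.5,
                       promoter_span = c(-1100L, 1100L),
                       canonical_mean = 100,
                       ectopic_mean = 50,
                       dispersion = 0.05,
                       polII_level = 10,
                       nuc_offsets = c(-250L, 130L),
                       frags_per_nuc = 25L,
                       tss_nuc_frags = 50L,
                       nuc_gain_prob_shifted = 0.8,
                       nuc_gain_prob_bound = 0.3,
                       dyad_jitter_sd = 8,
                       mnase_frag_len = c(115L, 185L),
                       mnase_bg_frags = 10L,
                       mnase_dup_frac = 0.03,
                       ribo_frags_per_gene = 150L,
                       uorf_frags = 120L,
                       uorf_prob = 0.7,
                       frame0_purity = 0.85,
                       ribo_frag_len = 30L,
                       rna_frags_per_gene = 60L,
                       seed = 1L) {
  shift_dist <- match.arg(shift_dist)
  if (is.null(scale_factors)) {
    base <- c(1.0, 1.2, 0.85, 1.1, 0.75, 1.3)
    scale_factors <- rep_len(base, 2L * replicates)
  }
  names(scale_factors) <- c(paste0("ctl_", seq_len(replicates)),
                            paste0("kd_", seq_len(replicates)))
  cfg <- as.list(environment())
  stopifnot(cfg$bg_rate > 0, cfg$canonical_mean > 0, cfg$ectopic_mean > 0,
            cfg$dispersion > 0, all(scale_factors > 0),
            cfg$frac_shifted >= 0, cfg$frac_shifted <= 1)
  if (shift_dist == "uniform" && shift_range[2] > -26L) {
    stop("uniform shift range reaches into the core +/-25 region")
  }
  if (shift_dist == "lognormal" && shift_clip[1] < 26L) {
    stop("lognormal shift clip reaches into the core +/-25 region")
  }
  class(cfg) <- c("SimConfig", "list")
  cfg
}

draw_shift_offsets <- function(n, cfg) {
  if (cfg$shift_dist == "uniform") {
    width <- cfg$shift_range[2] - cfg$shift_range[1] + 1L
    cfg$shift_range[2] - sample.int(width, n, replace = TRUE) + 1L
  } else {
    d <- round(cfg$shift_median * exp(stats::rnorm(n, 0, cfg$shift_sigma)))
    -pmin(pmax(d, cfg$shift_clip[1]), cfg$shift_clip[2])
  }
}

plant_motif <- function(seqs, chrom, pos, strand, motif) {
  # place `motif` on the sense strand so that its first base sits at sense
  # offset 0 of `pos`
  if (strand == "-") {
    motif <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    pos <- pos - nchar(motif) + 1L
  }
  substr(seqs[[chrom]], pos + 1L, pos + nchar(motif)) <- motif
  seqs
}

nb_draw <- function(mu, dispersion) {
  stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

#' Simulate spike-in counts with known scale factors
#'
#' Counts for spike i in sample s are Poisson with mean
#' `base[i] * factors[s]` (spec: depth times true factor).
#'
#' @param base expected per-spike reads at factor 1.
#' @param factors named per-sample true scale factors.
#' @return Count matrix (spikes x samples).
#' @export
simulate_spike_counts <- function(base, factors) {
  m <- vapply(factors, function(f) stats::rpois(length(base), base * f),
              numeric(length(base)))
  rownames(m) <- paste0("spike_", seq_along(base))
  m
}

#' Generate a synthetic multi-omics dataset with ground truth
#'
#' Writes, under `out_dir`: `genome.fa`, `annotation.tsv`, per-sample
#' strand-specific Start-Seq 5'-end bedGraphs
#' (`startseq_<sample>_<plus|minus>.bedgraph`), `spikes.tsv`, `samples.tsv`
#' (condition, nominal depth, true factor), `mnase_<ctl|kd>.bed`,
#' `ribo_<ctl|kd>.bed`, `rna_ctl.bed`, `polii.bedgraph`, `nfy_peaks.bed`,
#' `truth.tsv`, and the resolved `sim_config.yaml`. Output is byte-identical
#' across runs with the same config (including its seed).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `dir`, `truth` (per-gene data.frame),
#'   `samples`, `annotation`, and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n <- cfg$n_genes
  per_chrom <- ceiling(n / cfg$n_chrom)
  chrom <- paste0("chr", rep(seq_len(cfg$n_chrom), each = per_chrom))[1:n]
  slot <- (seq_len(n) - 1L) %% per_chrom
  strand <- sample(c("+", "-"), n, replace = TRUE)
  locus_start <- slot * cfg$locus_size
  tss <- ifelse(strand == "+", locus_start + 2600L,
                locus_start + cfg$locus_size - 2601L)
  gene_len <- 2400L
  start <- ifelse(strand == "+", tss, tss - gene_len + 1L)
  end <- ifelse(strand == "+", tss + gene_len, tss + 1L)
  cds_start <- offset_to_position(300L, tss, strand)
  gene_id <- sprintf("g%03d", seq_len(n))

  anno <- transcript_annotation(data.frame(
    transcript_id = paste0(gene_id, ".1"), gene_id = gene_id,
    chrom = chrom, start = start, end = end, strand = strand,
    cds_start = cds_start, low_confidence = FALSE,
    stringsAsFactors = FALSE))

  # --- planted truth -------------------------------------------------------
  n_shift <- round(cfg$frac_shifted * n)
  shifted_idx <- sort(sample.int(n, n_shift))
  shift_offset <- rep(NA_integer_, n)
  shift_offset[shifted_idx] <- as.integer(draw_shift_offsets(n_shift, cfg))
  bound <- logical(n)
  bound[shifted_idx] <- TRUE
  n_extra <- round(cfg$frac_bound_extra * n)
  unbound_pool <- setdiff(seq_len(n), shifted_idx)
  bound[sample(unbound_pool, min(n_extra, length(unbound_pool)))] <- TRUE
  nuc_gain <- logical(n)
  nuc_gain[shifted_idx] <-
    stats::runif(n_shift) < cfg$nuc_gain_prob_shifted
  bound_ns <- which(bound & is.na(shift_offset))
  nuc_gain[bound_ns] <- stats::runif(length(bound_ns)) < cfg$nuc_gain_prob_bound
  uorf <- rep(NA_integer_, n)  # sense offset of the planted ATG's A
  has_uorf <- shifted_idx[stats::runif(n_shift) < cfg$uorf_prob]
  uorf[has_uorf] <- shift_offset[has_uorf] + 6L

  # --- genome sequence -----------------------------------------------------
  chrom_len <- per_chrom * cfg$locus_size
  seqs <- stats::setNames(
    vapply(seq_len(cfg$n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    }, character(1)),
    paste0("chr", seq_len(cfg$n_chrom)))
  for (i in seq_len(n)) {
    # YR initiator (CA) spanning sense offsets -1/0 of the canonical TSS
    seqs <- plant_motif(seqs, chrom[i],
                        offset_to_position(-1L, tss[i], strand[i]),
                        strand[i], "CA")
    # start codon of the canonical ORF
    seqs <- plant_motif(seqs, chrom[i], cds_start[i], strand[i], "ATG")
    if (bound[i]) {
      seqs <- plant_motif(seqs, chrom[i],
                          offset_to_position(-80L, tss[i], strand[i]),
                          strand[i], "CCAAT")
    }
    if (!is.na(shift_offset[i])) {
      seqs <- plant_motif(
        seqs, chrom[i],
        offset_to_position(shift_offset[i] - 1L, tss[i], strand[i]),
        strand[i], "CA")
    }
    if (!is.na(uorf[i])) {
      seqs <- plant_motif(seqs, chrom[i],
                          offset_to_position(uorf[i], tss[i], strand[i]),
                          strand[i], "ATG")
    }
  }
  write_genome_fasta(seqs, file.path(out_dir, "genome.fa"))
  write_annotation(anno, file.path(out_dir, "annotation.tsv"))

  samples <- names(cfg$scale_factors)
  condition <- ifelse(grepl("^ctl", samples), "ctl", "kd")

  # --- Start-Seq 5'-end tracks --------------------------------------------
  span <- seq.int(cfg$promoter_span[1], cfg$promoter_span[2])
  for (s in seq_along(samples)) {
    f <- cfg$scale_factors[s]
    tracks <- list("+" = signal_track("+"), "-" = signal_track("-"))
    for (i in seq_len(n)) {
      mu <- rep(cfg$bg_rate, length(span))
      mu[span == 0L] <- cfg$canonical_mean
      if (condition[s] == "kd" && !is.na(shift_offset[i])) {
        mu[span == shift_offset[i]] <- mu[span == shift_offset[i]] +
          cfg$ectopic_mean
      }
      counts <- nb_draw(mu * f, cfg$dispersion)
      nz <- counts > 0
      if (!any(nz)) next
      pos <- offset_to_position(span[nz], tss[i], strand[i])
      tracks[[strand[i]]] <- track_add(tracks[[strand[i]]], chrom[i],
                                       pos, counts[nz])
    }
    write_bedgraph(tracks[["+"]],
                   file.path(out_dir, paste0("startseq_", samples[s],
                                             "_plus.bedgraph")))
    write_bedgraph(tracks[["-"]],
                   file.path(out_dir, paste0("startseq_", samples[s],
                                             "_minus.bedgraph")))
  }

  # --- spike-ins -----------------------------------------------------------
  spike_base <- cfg$spike_mean *
    exp(seq(-1, 1, length.out = cfg$n_spikes))
  spikes <- simulate_spike_counts(spike_base, cfg$scale_factors)
  write_spike_table(spikes, file.path(out_dir, "spikes.tsv"))
  samples_df <- data.frame(sample = samples, condition = condition,
                           total_mapped = 1e7,
                           true_factor = unname(cfg$scale_factors),
                           stringsAsFactors = FALSE)
  utils::write.table(samples_df, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- Pol II coverage and binding peaks -----------------------------------
  pol <- signal_track("*", "polII")
  for (i in seq_len(n)) {
    pol <- track_add(pol, chrom[i], seq.int(tss[i] - 600L, tss[i] + 600L),
                     cfg$polII_level)
  }
  write_bedgraph(pol, file.path(out_dir, "polii.bedgraph"))
  bi <- which(bound)
  peak_start <- ifelse(strand[bi] == "+", tss[bi] - 120L, tss[bi] + 60L)
  peak_end <- ifelse(strand[bi] == "+", tss[bi] - 59L, tss[bi] + 121L)
  writeLines(sprintf("%s\t%d\t%d", chrom[bi], peak_start, peak_end),
             file.path(out_dir, "nfy_peaks.bed"))

  # --- MNase fragments -----------------------------------------------------
  make_mnase <- function(cond) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      dyads <- cfg$nuc_offsets
      counts <- rep(cfg$frags_per_nuc, length(dyads))
      if (cond == "kd" && nuc_gain[i]) {
        dyads <- c(dyads, 0L)
        counts <- c(counts, cfg$tss_nuc_frags)
      }
      centers <- offset_to_position(rep(dyads, counts), tss[i], strand[i]) +
        round(stats::rnorm(sum(counts), 0, cfg$dyad_jitter_sd))
      bg <- locus_start[i] +
        sample.int(cfg$locus_size - 200L, cfg$mnase_bg_frags) + 100L
      centers <- c(centers, bg)
      len <- sample(seq.int(cfg$mnase_frag_len[1], cfg$mnase_frag_len[2]),
                    length(centers), replace = TRUE)
      fs <- pmax(centers - len %/% 2L, 0L)
      rows[[i]] <- data.frame(chrom = chrom[i], start = fs, end = fs + len,
                              strand = sample(c("+", "-"), length(fs),
                                              replace = TRUE),
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    dup <- df[stats::runif(nrow(df)) < cfg$mnase_dup_frac, , drop = FALSE]
    rbind(df, dup)
  }
  for (cond in c("ctl", "kd")) {
    frags <- make_mnase(cond)
    write_fragments_bed(
      fragment_set(frags$chrom, frags$start, frags$end, frags$strand),
      file.path(out_dir, paste0("mnase_", cond, ".bed")))
  }

  # --- Ribo-Seq footprints and RNA-Seq-like control ------------------------
  draw_orf_frags <- function(i, anchor, n_frags, n_codons) {
    codon <- sample.int(n_codons, n_frags, replace = TRUE,
                        prob = (n_codons:1)) - 1L
    inframe <- stats::runif(n_frags) < cfg$frame0_purity
    wobble <- ifelse(inframe, 0L, sample(1:2, n_frags, replace = TRUE))
    psite_off <- 3L * codon + wobble
    psite <- offset_to_position(psite_off, anchor, strand[i])
    if (strand[i] == "+") {
      fs <- psite - 12L
      data.frame(chrom = chrom[i], start = fs, end = fs + cfg$ribo_frag_len,
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      fe <- psite + 13L
      data.frame(chrom = chrom[i], start = fe - cfg$ribo_frag_len, end = fe,
                 strand = "-", stringsAsFactors = FALSE)
    }
  }
  make_ribo <- function(cond) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      r <- draw_orf_frags(i, cds_start[i], cfg$ribo_frags_per_gene, 60L)
      if (cond == "kd" && !is.na(uorf[i])) {
        n_codons <- max((-25L - uorf[i]) %/% 3L, 5L)
        up <- draw_orf_frags(i, offset_to_position(uorf[i], tss[i],
                                                   strand[i]),
                             cfg$uorf_frags, min(n_codons, 20L))
        r <- rbind(r, up)
      }
      rows[[i]] <- r
    }
    do.call(rbind, rows)
  }
  for (cond in c("ctl", "kd")) {
    frags <- make_ribo(cond)
    frags$start <- pmax(frags$start, 0L)
    write_fragments_bed(
      fragment_set(frags$chrom, frags$start, frags$end, frags$strand),
      file.path(out_dir, paste0("ribo_", cond, ".bed")))
  }
  rna_rows <- lapply(seq_len(n), function(i) {
    off <- sample.int(600L, cfg$rna_frags_per_gene, replace = TRUE) - 1L
    psite <- offset_to_position(off, cds_start[i], strand[i])
    if (strand[i] == "+") {
      fs <- psite - 12L
      data.frame(chrom = chrom[i], start = fs, end = fs + cfg$ribo_frag_len,
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      fe <- psite + 13L
      data.frame(chrom = chrom[i], start = fe - cfg$ribo_frag_len, end = fe,
                 strand = "-", stringsAsFactors = FALSE)
    }
  })
  rna <- do.call(rbind, rna_rows)
  rna$start <- pmax(rna$start, 0L)
  write_fragments_bed(fragment_set(rna$chrom, rna$start, rna$end, rna$strand),
                      file.path(out_dir, "rna_ctl.bed"))

  # --- truth ---------------------------------------------------------------
  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
    shifted = !is.na(shift_offset), shift_offset = shift_offset,
    bound = bound, nuc_gain = nuc_gain, uorf_offset = uorf,
    uorf_pos = ifelse(is.na(uorf), NA_integer_,
                      offset_to_position(uorf, tss, strand)),
    ectopic_pos = ifelse(is.na(shift_offset), NA_integer_,
                         offset_to_position(shift_offset, tss, strand)),
    stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- cfg
  cfg_out$scale_factors <- as.list(cfg_out$scale_factors)
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "sim_config.yaml"))

  invisible(list(dir = out_dir, truth = truth, samples = samples_df,
                 annotation = anno, config = cfg))
}
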