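# Ectopic initiation detection: 10-nt bins tiling the promoter, a
# spike-anchored negative-binomial differential test per bin, BH correction
# over all retained (gene, bin) pairs, and per-gene selection of the ectopic
# base inside the winning bin.

#' Bin 5'-end counts around an observed TSS
#'
#' Tiles the inclusive offset region `bin_region` (default -995..+995) with
#' `bin_width`-nt bins starting at the lower bound: bin k covers offsets
#' `[-995 + 10k, -995 + 10k + 9]`. With the defaults the 1991-nt region is not
#' divisible by 10, so 199 bins cover offsets -995..+994 and the single
#' farthest downstream base is not tiled.
#'
#' @param call one row of an `ObservedTssCall` data.frame (the gene's observed
#'   TSS provides the anchor, chromosome, and strand).
#' @param tracks named list of raw 5'-end `SignalTrack` pairs, one element per
#'   sample, each a list with elements `"+"` and `"-"`.
#' @param cfg a [pipeline_config()].
#' @return A `BinStat` data.frame with `gene_id`, `bin` (0-based index),
#'   `off_lo`, `off_hi` (inclusive offsets), and one raw count column per
#'   sample.
#' @export
bin_counts <- function(call, tracks, cfg = pipeline_config()) {
  w <- cfg$bin_width
  lo <- cfg$bin_region[1]
  hi <- cfg$bin_region[2]
  n_bins <- (hi - lo + 1L) %/% w
  span_hi <- lo + n_bins * w - 1L
  strand <- call$strand
  counts <- vapply(tracks, function(pair) {
    v <- track_window(pair[[strand]], call$chrom, call$observed, strand,
                      lo, span_hi)
    as.numeric(rowsum(v, rep(seq_len(n_bins), each = w)))
  }, numeric(n_bins))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = n_bins)
  colnames(counts) <- names(tracks)
  out <- data.frame(
    gene_id = call$gene_id,
    bin = seq_len(n_bins) - 1L,
    off_lo = lo + (seq_len(n_bins) - 1L) * w,
    off_hi = lo + seq_len(n_bins) * w - 1L,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(counts))
}

#' Flag bins excluded from the differential test
#'
#' A bin is excluded when (i) the distance from its midpoint to the nearest
#' *other* observed TSS (any gene, same strand) is smaller than to its own
#' TSS, or (ii) its offset range intersects the inclusive core region
#' `core_exclusion` (default -25..+24) around its own TSS. The core exclusion
#' is what guarantees that no ectopic call ever falls within 25 nt of the
#' canonical TSS.
#'
#' @param bins a `BinStat` data.frame from [bin_counts()].
#' @param call the gene's `ObservedTssCall` row (anchor of `bins`).
#' @param all_calls `ObservedTssCall` data.frame of every observed TSS (used
#'   for the nearer-other-TSS rule).
#' @param cfg a [pipeline_config()].
#' @return `bins` with logical `excluded` and character `exclude_reason`
#'   (`"nearer_other_tss"`, `"core_region"`, or `NA`) columns.
#' @export
exclude_bins <- function(bins, call, all_calls, cfg = pipeline_config()) {
  mid_off <- (bins$off_lo + bins$off_hi) / 2
  mid_pos <- offset_to_position(mid_off, call$observed, call$strand)
  others <- all_calls[all_calls$chrom == call$chrom &
                        all_calls$strand == call$strand &
                        all_calls$observed != call$observed, , drop = FALSE]
  nearer_other <- rep(FALSE, nrow(bins))
  if (nrow(others) > 0) {
    d_other <- vapply(mid_pos, function(p) min(abs(others$observed - p)),
                      numeric(1))
    nearer_other <- d_other < abs(mid_pos - call$observed)
  }
  core <- bins$off_lo <= cfg$core_exclusion[2] &
    bins$off_hi >= cfg$core_exclusion[1]
  bins$excluded <- core | nearer_other
  bins$exclude_reason <- ifelse(core, "core_region",
                                ifelse(nearer_other, "nearer_other_tss",
                                       NA_character_))
  bins
}

# ---------------------------------------------------------------------------
# Negative-binomial test machinery

# Method-of-moments dispersion per bin on size-factor-normalized counts:
# alpha = (pooled within-condition variance - mean * mean(1/s)) / mean^2.
mom_dispersion <- function(norm_counts, size_factors, condition) {
  z_bar <- mean(1 / size_factors)
  mu <- rowMeans(norm_counts)
  lv <- lapply(unique(condition), function(cc) {
    sub <- norm_counts[, condition == cc, drop = FALSE]
    n_c <- ncol(sub)
    list(ss = rowSums((sub - rowMeans(sub))^2), df = n_c - 1L)
  })
  ss <- Reduce(`+`, lapply(lv, `[[`, "ss"))
  df <- sum(vapply(lv, `[[`, integer(1), "df"))
  if (df < 1L) stop("dispersion estimation needs >= 2 replicates per condition")
  v <- ss / df
  alpha <- (v - z_bar * mu) / mu^2
  alpha[!is.finite(alpha)] <- NA_real_
  list(mu = mu, alpha = alpha)
}

# Least-squares fit of the mean-dispersion trend alpha(mu) = a0 + a1/mu
# across all bins with positive mean (raw method-of-moments values, including
# negative ones, enter the fit so the trend itself is not biased upward).
fit_dispersion_trend <- function(mu, alpha) {
  ok <- is.finite(mu) & mu > 0 & is.finite(alpha)
  if (sum(ok) >= 3L && stats::sd(1 / mu[ok]) > 0) {
    co <- stats::coef(stats::lm.fit(cbind(1, 1 / mu[ok]),
                                    alpha[ok]))
  } else {
    co <- c(max(mean(alpha[ok]), 0, na.rm = TRUE), 0)
  }
  function(m) pmax(co[1] + co[2] / m, 0)
}

# Exact conditional NB test on condition totals: given K = K_A + K_B, the
# two-sided p-value is the probability mass of all splits (a, K - a) no more
# likely than the observed one, under NB laws for the per-condition totals
# whose mean and variance follow from the common concentration q and the
# dispersion alpha.
nb_exact_test <- function(kA, kB, sA, sB, s2A, s2B, alpha) {
  K <- kA + kB
  if (K == 0) return(1)
  q <- K / (sA + sB)
  a <- 0:K
  pA <- nb_total_prob(a, q, sA, s2A, alpha)
  pB <- nb_total_prob(K - a, q, sB, s2B, alpha)
  joint <- pA * pB
  obs <- joint[kA + 1L]
  tot <- sum(joint)
  if (tot <= 0) return(1)
  min(1, sum(joint[joint <= obs * (1 + 1e-8)]) / tot)
}

# Probability mass of a condition total: mean q * S, variance
# q * S + alpha * q^2 * S2 (S = sum of size factors, S2 = sum of squares);
# Poisson limit when the dispersion term vanishes.
nb_total_prob <- function(x, q, S, S2, alpha) {
  mu <- q * S
  extra <- alpha * q^2 * S2
  if (extra <= 0) return(stats::dpois(x, mu))
  size <- mu^2 / extra
  stats::dnbinom(x, size = size, mu = mu)
}

#' Binned negative-binomial differential test
#'
#' For every retained bin, tests knockdown against control read counts with a
#' negative-binomial model anchored on spike-derived size factors. The per-bin
#' dispersion is the maximum of a method-of-moments estimate (on normalized
#' counts, pooled across conditions) and a mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` fitted across all bins by least squares; p-values
#' come from the exact conditional test on condition totals, and
#' Benjamini-Hochberg correction is applied jointly across all retained
#' (gene, bin) pairs. The reported log2 fold change uses size-factor-
#' normalized condition means with a pseudocount of 0.5 on each mean.
#'
#' @param bins a `BinStat` data.frame (rows may span many genes) as produced
#'   by [bin_counts()] + [exclude_bins()]; if no `excluded` column is present
#'   all bins are tested.
#' @param size_factors named per-sample size factors (see
#'   [size_factors_from_spikes()]).
#' @param condition character vector parallel to `size_factors`, with exactly
#'   two levels; the *second* sorted level is treated as knockdown unless
#'   `kd_level` is given.
#' @param kd_level which condition level is the knockdown (numerator of the
#'   fold change).
#' @return `bins` with added columns `base_mean`, `dispersion`, `log2fc`,
#'   `p`, `padj` (NA for excluded bins).
#' @export
nb_bin_test <- function(bins, size_factors, condition, kd_level = NULL) {
  samples <- names(size_factors)
  stopifnot(!is.null(samples), all(samples %in% names(bins)),
            length(condition) == length(size_factors))
  lev <- sort(unique(condition))
  stopifnot(length(lev) == 2L)
  if (is.null(kd_level)) kd_level <- lev[2]
  stopifnot(kd_level %in% lev)
  ctl_level <- setdiff(lev, kd_level)
  if (min(table(condition)) < 2L) {
    stop("dispersion estimation needs >= 2 replicates per condition")
  }

  counts <- as.matrix(bins[, samples, drop = FALSE])
  retained <- if ("excluded" %in% names(bins)) !bins$excluded else
    rep(TRUE, nrow(bins))

  norm <- sweep(counts, 2L, size_factors, `/`)
  is_kd <- condition == kd_level
  mean_kd <- rowMeans(norm[, is_kd, drop = FALSE])
  mean_ctl <- rowMeans(norm[, !is_kd, drop = FALSE])
  bins$base_mean <- rowMeans(norm)
  bins$log2fc <- log2((mean_kd + 0.5) / (mean_ctl + 0.5))

  disp <- mom_dispersion(norm, size_factors, condition)
  trend <- fit_dispersion_trend(disp$mu[retained], disp$alpha[retained])
  alpha <- pmax(disp$alpha, trend(disp$mu), 1e-8)
  alpha[is.na(alpha)] <- 1e-8
  bins$dispersion <- ifelse(retained, alpha, NA_real_)

  sA <- sum(size_factors[!is_kd]); s2A <- sum(size_factors[!is_kd]^2)
  sB <- sum(size_factors[is_kd]); s2B <- sum(size_factors[is_kd]^2)
  kA <- round(rowSums(counts[, !is_kd, drop = FALSE]))
  kB <- round(rowSums(counts[, is_kd, drop = FALSE]))

  p <- rep(NA_real_, nrow(bins))
  idx <- which(retained)
  p[idx] <- vapply(idx, function(i) {
    nb_exact_test(kA[i], kB[i], sA, sB, s2A, s2B, alpha[i])
  }, numeric(1))
  bins$p <- p
  bins$padj <- NA_real_
  bins$padj[idx] <- stats::p.adjust(p[idx], method = "BH")
  attr(bins, "kd_level") <- kd_level
  attr(bins, "ctl_level") <- ctl_level
  bins
}

#' Select the ectopic TSS from tested bins of one gene
#'
#' Among significant bins (positive log2 fold change and adjusted p below
#' `padj_threshold`), keeps the one with the lowest adjusted p (ties: lowest
#' raw p, then nearest the observed TSS). Within the winning bin the ectopic
#' TSS is the position with the highest total knockdown 5'-end count across
#' samples; count ties go to the position closest to the observed TSS, then
#' upstream.
#'
#' @param bins tested `BinStat` rows of one gene (from [nb_bin_test()]).
#' @param call the gene's `ObservedTssCall` row.
#' @param kd_tracks named list of raw knockdown 5'-end track pairs (elements
#'   `"+"`/`"-"` per sample).
#' @param cfg a [pipeline_config()].
#' @return One-row `EctopicTssCall` data.frame (`gene_id`, `position`,
#'   `offset`, `bin`, `padj`, `shift_distance` — positive upstream), or `NULL`
#'   when no bin is significant.
#' @export
select_ectopic <- function(bins, call, kd_tracks, cfg = pipeline_config()) {
  ok <- !is.na(bins$padj) & bins$padj < cfg$padj_threshold & bins$log2fc > 0
  if (!any(ok)) return(NULL)
  cand <- bins[ok, , drop = FALSE]
  mid <- abs((cand$off_lo + cand$off_hi) / 2)
  ord <- order(cand$padj, cand$p, mid)
  win <- cand[ord[1], , drop = FALSE]

  offs <- seq.int(win$off_lo, win$off_hi)
  kd_sum <- Reduce(`+`, lapply(kd_tracks, function(pair) {
    track_window(pair[[call$strand]], call$chrom, call$observed, call$strand,
                 win$off_lo, win$off_hi)
  }))
  best <- kd_sum == max(kd_sum)
  best <- best & abs(offs) == min(abs(offs)[best])
  off <- min(offs[best])
  data.frame(
    gene_id = call$gene_id,
    position = offset_to_position(off, call$observed, call$strand),
    offset = off,
    bin = win$bin,
    padj = win$padj,
    shift_distance = -off,
    stringsAsFactors = FALSE
  )
}

#' Full per-gene ectopic TSS caller
#'
#' Orchestrates [bin_counts()], [exclude_bins()], [nb_bin_test()] (BH jointly
#' across all genes) and [select_ectopic()] over a set of observed TSS calls.
#'
#' @param calls `ObservedTssCall` data.frame (typically deduplicated).
#' @param tracks named list of raw 5'-end track pairs for *all* samples.
#' @param size_factors named per-sample size factors.
#' @param condition condition label per sample (two levels).
#' @param kd_level knockdown level name (defaults to second sorted level).
#' @param cfg a [pipeline_config()].
#' @return List with `bins` (the full tested `BinStat` table) and `calls`
#'   (`EctopicTssCall` data.frame, possibly empty).
#' @export
call_ectopic_tss <- function(calls, tracks, size_factors, condition,
                             kd_level = NULL, cfg = pipeline_config()) {
  if (nrow(calls) == 0) {
    empty <- data.frame(gene_id = character(), position = integer(),
                        offset = integer(), bin = integer(), padj = numeric(),
                        shift_distance = integer(), stringsAsFactors = FALSE)
    class(empty) <- c("EctopicTssCall", "data.frame")
    return(list(bins = data.frame(), calls = empty))
  }
  bin_list <- lapply(seq_len(nrow(calls)), function(i) {
    b <- bin_counts(calls[i, ], tracks, cfg)
    exclude_bins(b, calls[i, ], calls, cfg)
  })
  bins <- do.call(rbind, bin_list)
  bins <- nb_bin_test(bins, size_factors, condition, kd_level)
  kd_level <- attr(bins, "kd_level")
  kd_tracks <- tracks[condition == kd_level]
  ect <- lapply(seq_len(nrow(calls)), function(i) {
    g <- bins[bins$gene_id == calls$gene_id[i], , drop = FALSE]
    select_ectopic(g, calls[i, ], kd_tracks, cfg)
  })
  ect <- do.call(rbind, ect[!vapply(ect, is.null, logical(1))])
  if (is.null(ect)) {
    ect <- data.frame(gene_id = character(), position = integer(),
                      offset = integer(), bin = integer(), padj = numeric(),
                      shift_distance = integer(), stringsAsFactors = FALSE)
  }
  class(ect) <- c("EctopicTssCall", "data.frame")
  list(bins = bins, calls = ect)
}

#' Maximum sliding-window read-count difference upstream of the TSS
#'
#' Maximum over `sliding_window`-nt windows (step 1 nt), fully contained in
#' the inclusive offset range `region` (default -900..-25), of the knockdown
#' minus control summed signal.
#'
#' @param call the gene's `ObservedTssCall` row.
#' @param control,kd `SignalTrack` pairs (elements `"+"`/`"-"`) of normalized
#'   mean condition signal.
#' @param region inclusive offset bounds searched (default `c(-900, -25)`).
#' @param cfg a [pipeline_config()].
#' @return The maximum windowed difference (scalar).
#' @export
sliding_max_difference <- function(call, control, kd,
                                   region = c(-900L, -25L),
                                   cfg = pipeline_config()) {
  w <- cfg$sliding_window
  strand <- call$strand
  cv <- track_window(control[[strand]], call$chrom, call$observed, strand,
                     region[1], region[2])
  kv <- track_window(kd[[strand]], call$chrom, call$observed, strand,
                     region[1], region[2])
  d <- kv - cv
  cs <- cumsum(c(0, d))
  max(cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)])
}

#' Assign genes to six groups by promoter binding strength
#'
#' Sextile assignment by ChIP read count in the `bound_window` around the
#' observed TSS; ties keep the stable input order (group 1 holds the lowest
#' counts, group 6 the highest).
#'
#' @param chip_counts numeric vector of per-gene ChIP read counts.
#' @return Integer group labels 1..6 parallel to `chip_counts`.
#' @export
chip_strength_bins <- function(chip_counts) {
  n <- length(chip_counts)
  r <- rank(chip_counts, ties.method = "first")
  as.integer(floor((r - 1) * 6 / n) + 1L)
}

#' Median shift distance and upstream fraction of ectopic calls
#'
#' @param ect an `EctopicTssCall` data.frame.
#' @return List with `n`, `median_shift` (median of upstream-positive shift
#'   distances) and `upstream_fraction`; all `NA`/empty when no calls.
#' @export
shift_summary <- function(ect) {
  if (nrow(ect) == 0) {
    return(list(n = 0L, median_shift = NA_real_,
                upstream_fraction = NA_real_))
  }
  list(n = nrow(ect),
       median_shift = stats::median(ect$shift_distance),
       upstream_fraction = mean(ect$offset < 0))
}
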