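#' Read a spike-in count table
#'
#' @param path TSV with one row per synthetic capped spike-in RNA and one
#'   column per sample; first column `spike_id`, header row of sample names.
#' @return Numeric matrix (rows = spikes, columns = samples).
#' @export
read_spike_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a spike-in count table
#' @param counts matrix (rows = spikes, columns = samples).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(counts, path) {
  df <- data.frame(spike_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spike-in regression normalization factor for one sample
#'
#' The factor is the slope of the least-squares regression through the origin
#' of the sample's depth-normalized spike-in counts on those of the reference
#' sample (the sample with the lowest total count):
#' `slope = sum(x * y) / sum(x^2)` with `x` = reference, `y` = sample.
#' Downstream tracks are *divided* by this factor to bring every sample onto
#' the reference scale (the reference's own factor is 1 by construction).
#'
#' @param sample_counts depth-normalized spike counts of the sample.
#' @param ref_counts depth-normalized spike counts of the reference sample.
#' @return The slope (positive scalar).
#' @export
spike_normalization_factor <- function(sample_counts, ref_counts) {
  stopifnot(length(sample_counts) == length(ref_counts),
            length(ref_counts) >= 2L)
  if (all(ref_counts == 0)) stop("all-zero reference spike counts")
  sum(ref_counts * sample_counts) / sum(ref_counts^2)
}

#' Spike-in normalization factors for all samples
#'
#' Depth-normalizes the raw spike counts (per `norm_denominator` total mapped
#' reads), picks the reference sample, and regresses every sample on it.
#'
#' @param counts raw spike count matrix (rows = spikes, columns = samples).
#' @param totals per-sample total mapped read counts (named or in column
#'   order).
#' @param ref reference sample: `"auto"` (the sample with the minimum total
#'   raw spike count) or a column name.
#' @param norm_denominator depth normalization target (default 1e7).
#' @return A `SpikeInSet` list with elements `counts` (raw), `depth_normalized`,
#'   `totals`, `reference`, and `factors` (named per-sample regression
#'   slopes; the reference's is exactly 1).
#' @export
spike_factors <- function(counts, totals, ref = "auto",
                          norm_denominator = 1e7) {
  stopifnot(ncol(counts) == length(totals), all(totals > 0))
  if (!is.null(names(totals))) totals <- totals[colnames(counts)]
  depth_norm <- sweep(counts, 2L, norm_denominator / totals, `*`)
  if (identical(ref, "auto")) {
    ref <- colnames(counts)[which.min(colSums(counts))]
  }
  stopifnot(ref %in% colnames(counts))
  factors <- vapply(colnames(counts), function(s) {
    spike_normalization_factor(depth_norm[, s], depth_norm[, ref])
  }, numeric(1))
  factors[ref] <- 1
  structure(list(counts = counts, depth_normalized = depth_norm,
                 totals = totals, reference = ref, factors = factors),
            class = "SpikeInSet")
}

#' @export
print.SpikeInSet <- function(x, ...) {
  cat(sprintf("SpikeInSet: %d spikes x %d samples (reference %s)\n",
              nrow(x$counts), ncol(x$counts), x$reference))
  print(round(x$factors, 4))
  invisible(x)
}

#' Median-of-ratios size factors from spike-in counts alone
#'
#' The size factor of sample `s` is the median over spikes of
#' `count[spike, s] / geometric mean over samples of count[spike, ]`,
#' computed on the spike-count matrix only so that the factors reflect the
#' spike-in anchor rather than genomic signal. Spikes with a zero count in
#' any sample are excluded from the geometric-mean reference set. These are
#' the size factors used by the binned negative-binomial test.
#'
#' @param counts raw spike count matrix (rows = spikes, columns = samples).
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors_from_spikes <- function(counts) {
  stopifnot(nrow(counts) >= 1L)
  keep <- apply(counts > 0, 1L, all)
  if (!any(keep)) stop("no spike has nonzero counts in every sample")
  m <- counts[keep, , drop = FALSE]
  log_geo <- rowMeans(log(m))
  ratios <- exp(sweep(log(m), 1L, log_geo, `-`))
  apply(ratios, 2L, stats::median)
}
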