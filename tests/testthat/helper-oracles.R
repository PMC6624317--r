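# Independent brute-force re-implementations used as oracles. These scan
# every offset with explicit loops and their own strand arithmetic; they share
# no selection or windowing code with the package.

oracle_value_at <- function(track, chrom, pos) {
  track_slice(track, chrom, pos, pos + 1L)
}

oracle_pos_at_offset <- function(tss, strand, off) {
  if (strand == "+") tss + off else tss - off
}

# Brute-force observed-TSS caller for a single transcript.
oracle_observed_one <- function(tss, strand, chrom, start5p, polII,
                                R = 1000L, W = 200L, P = 250L,
                                ratio = 2 / 3, min_reads = 5) {
  tr <- start5p[[strand]]
  if (!track_has_chrom(tr, chrom)) {
    return(list(observed = tss, source = "annotation_kept"))
  }
  offs <- -R:R
  counts <- vapply(offs, function(o) {
    oracle_value_at(tr, chrom, oracle_pos_at_offset(tss, strand, o))
  }, numeric(1))

  better <- function(o1, c1, o2, c2) {
    # is candidate 1 strictly better than candidate 2?
    if (c1 != c2) return(c1 > c2)
    if (abs(o1) != abs(o2)) return(abs(o1) < abs(o2))
    o1 < o2
  }
  argmax <- function(idx) {
    best <- idx[1]
    for (i in idx[-1]) {
      if (better(offs[i], counts[i], offs[best], counts[best])) best <- i
    }
    best
  }

  a <- argmax(seq_along(offs))

  best_s <- NA
  best_sum <- -Inf
  for (s in 1:(length(offs) - W + 1L)) {
    wsum <- sum(counts[s:(s + W - 1L)])
    mid <- offs[s] + (W - 1) / 2
    take <- if (wsum > best_sum) TRUE else if (wsum == best_sum) {
      bmid <- offs[best_s] + (W - 1) / 2
      abs(mid) < abs(bmid)
    } else FALSE
    if (take) { best_s <- s; best_sum <- wsum }
  }
  b <- argmax(best_s:(best_s + W - 1L))

  if (abs(offs[a]) <= abs(offs[b])) {
    sel <- a; src <- "startseq_primary"
  } else {
    sel <- b; src <- "startseq_density"
  }

  polsum_at <- function(center) {
    s <- 0
    for (p in (center - P):(center + P)) {
      s <- s + oracle_value_at(polII, chrom, p)
    }
    s
  }
  sel_pos <- oracle_pos_at_offset(tss, strand, offs[sel])
  if (polsum_at(sel_pos) < ratio * polsum_at(tss)) {
    sel <- argmax(which(offs >= -P & offs <= P))
    src <- "polII_rescued"
  }
  if (counts[sel] < min_reads) {
    return(list(observed = tss, source = "annotation_lowreads"))
  }
  list(observed = oracle_pos_at_offset(tss, strand, offs[sel]), source = src)
}

# Brute-force bin count matrix: loops every offset of every bin.
oracle_bin_counts <- function(call, tracks, lo = -995L, hi = 995L, w = 10L) {
  n_bins <- (hi - lo + 1L) %/% w
  m <- matrix(0, n_bins, length(tracks),
              dimnames = list(NULL, names(tracks)))
  for (k in seq_len(n_bins)) {
    offs <- (lo + (k - 1L) * w):(lo + k * w - 1L)
    for (s in seq_along(tracks)) {
      tr <- tracks[[s]][[call$strand]]
      for (o in offs) {
        m[k, s] <- m[k, s] +
          oracle_value_at(tr, call$chrom,
                          oracle_pos_at_offset(call$observed, call$strand, o))
      }
    }
  }
  m
}

# Brute-force exclusion flags (midpoint rule + core intersection).
oracle_excluded <- function(call, all_calls, lo = -995L, hi = 995L, w = 10L,
                            core = c(-25L, 24L)) {
  n_bins <- (hi - lo + 1L) %/% w
  out <- logical(n_bins)
  for (k in seq_len(n_bins)) {
    o_lo <- lo + (k - 1L) * w
    o_hi <- o_lo + w - 1L
    if (o_lo <= core[2] && o_hi >= core[1]) { out[k] <- TRUE; next }
    mid <- oracle_pos_at_offset(call$observed, call$strand,
                                (o_lo + o_hi) / 2)
    d_own <- abs(mid - call$observed)
    for (j in seq_len(nrow(all_calls))) {
      if (all_calls$chrom[j] == call$chrom &&
          all_calls$strand[j] == call$strand &&
          all_calls$observed[j] != call$observed &&
          abs(mid - all_calls$observed[j]) < d_own) {
        out[k] <- TRUE
        break
      }
    }
  }
  out
}

# Brute-force ectopic selection given tested bins of one gene.
oracle_select <- function(bins, call, kd_tracks, padj_max = 0.1) {
  best <- NULL
  for (r in seq_len(nrow(bins))) {
    if (is.na(bins$padj[r]) || bins$padj[r] >= padj_max ||
        bins$log2fc[r] <= 0) next
    if (is.null(best)) { best <- r; next }
    mid_r <- abs((bins$off_lo[r] + bins$off_hi[r]) / 2)
    mid_b <- abs((bins$off_lo[best] + bins$off_hi[best]) / 2)
    if (bins$padj[r] < bins$padj[best] ||
        (bins$padj[r] == bins$padj[best] && bins$p[r] < bins$p[best]) ||
        (bins$padj[r] == bins$padj[best] && bins$p[r] == bins$p[best] &&
           mid_r < mid_b)) {
      best <- r
    }
  }
  if (is.null(best)) return(NULL)
  offs <- bins$off_lo[best]:bins$off_hi[best]
  tot <- vapply(offs, function(o) {
    s <- 0
    for (pair in kd_tracks) {
      s <- s + oracle_value_at(pair[[call$strand]], call$chrom,
                               oracle_pos_at_offset(call$observed,
                                                    call$strand, o))
    }
    s
  }, numeric(1))
  sel <- offs[1]
  for (i in seq_along(offs)[-1]) {
    o <- offs[i]
    if (tot[i] > tot[offs == sel] ||
        (tot[i] == tot[offs == sel] && abs(o) < abs(sel)) ||
        (tot[i] == tot[offs == sel] && abs(o) == abs(sel) && o < sel)) {
      sel <- o
    }
  }
  list(offset = sel, bin = bins$bin[best])
}
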