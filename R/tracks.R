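#' Per-base signal track
#'
#' The universal carrier for base-resolution signal: Start-Seq 5' end counts,
#' MNase fragment centers, Ribo-Seq P-sites, Pol II coverage, conservation
#' scores. A track holds one numeric vector per chromosome (index i = 0-based
#' position i-1), a strand slot (`"+"`, `"-"`, or `"*"` for unstranded), a
#' label, a normalization state, and a `default` value returned for positions
#' never written (0 for count tracks; `NA` for score tracks where absent means
#' missing, not zero).
#'
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param label free-text description.
#' @param norm normalization state: `"raw"`, `"per10M"` or `"spike"`.
#' @param default value of unwritten positions (0 or `NA_real_`).
#' @return A `SignalTrack` object.
#' @export
signal_track <- function(strand = "*", label = "", norm = "raw", default = 0) {
  stopifnot(strand %in% c("+", "-", "*"))
  structure(list(values = list(), strand = strand, label = label,
                 norm = norm, default = default),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack '%s' [strand %s, %s]: %d chromosome(s), total %g\n",
              x$label, x$strand, x$norm, length(x$values), track_total(x)))
  invisible(x)
}

grow_chrom <- function(track, chrom, need) {
  v <- track$values[[chrom]]
  if (is.null(v)) v <- rep(track$default, 0)
  if (length(v) < need) v <- c(v, rep(track$default, need - length(v)))
  v
}

#' Accumulate values into a track
#'
#' Adds `value` at each 0-based `pos` (duplicated positions accumulate).
#' On `NA`-default score tracks the positions are set rather than added.
#'
#' @param track a `SignalTrack`.
#' @param chrom chromosome name.
#' @param pos 0-based positions (integer vector).
#' @param value numeric scalar or vector parallel to `pos`.
#' @return The updated track.
#' @export
track_add <- function(track, chrom, pos, value = 1) {
  if (length(pos) == 0L) return(track)
  pos <- as.integer(pos)
  stopifnot(all(pos >= 0L))
  if (length(value) == 1L) value <- rep(as.numeric(value), length(pos))
  v <- grow_chrom(track, chrom, max(pos) + 1L)
  if (is.na(track$default)) {
    v[pos + 1L] <- value
  } else {
    agg <- rowsum(value, pos)
    idx <- as.integer(rownames(agg)) + 1L
    v[idx] <- v[idx] + agg[, 1L]
  }
  track$values[[chrom]] <- v
  track
}

#' Extract a half-open genomic slice of a track
#'
#' Returns the values over `[start, end)` (0-based); positions outside the
#' stored range (including negative coordinates) yield the track default.
#'
#' @param track a `SignalTrack`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return Numeric vector of length `end - start`.
#' @export
track_slice <- function(track, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end >= start)
  out <- rep(track$default, end - start)
  v <- track$values[[chrom]]
  if (is.null(v)) return(out)
  lo <- max(start, 0L)
  hi <- min(end, length(v))
  if (hi > lo) out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  out
}

#' Strand-oriented inclusive offset window of a track
#'
#' Values over inclusive offsets `off_lo..off_hi` relative to `anchor` in the
#' direction of `strand` (element 1 is offset `off_lo`).
#'
#' @param track a `SignalTrack`.
#' @param chrom chromosome name.
#' @param anchor 0-based anchor position.
#' @param strand `"+"` or `"-"`.
#' @param off_lo,off_hi inclusive offset bounds (`off_lo <= off_hi`).
#' @return Numeric vector of length `off_hi - off_lo + 1`.
#' @export
track_window <- function(track, chrom, anchor, strand, off_lo, off_hi) {
  stopifnot(off_lo <= off_hi, strand %in% c("+", "-"))
  if (strand == "+") {
    track_slice(track, chrom, anchor + off_lo, anchor + off_hi + 1L)
  } else {
    rev(track_slice(track, chrom, anchor - off_hi, anchor - off_lo + 1L))
  }
}

#' Total signal mass of a track
#' @param track a `SignalTrack`.
#' @return Sum of all stored values (`NA`s of score tracks ignored).
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(v) sum(v, na.rm = TRUE), numeric(1)))
}

#' Does the track carry any values for a chromosome?
#' @param track a `SignalTrack`.
#' @param chrom chromosome name.
#' @return Logical.
#' @export
track_has_chrom <- function(track, chrom) {
  !is.null(track$values[[chrom]])
}

#' Scale every value of a track by a constant
#' @param track a `SignalTrack`.
#' @param factor multiplicative constant.
#' @param norm new normalization state label (default keeps current).
#' @return The scaled track.
#' @export
track_scale <- function(track, factor, norm = track$norm) {
  track$values <- lapply(track$values, function(v) v * factor)
  track$norm <- norm
  track
}

#' Normalize a track per ten million mapped reads
#'
#' Multiplies every value by `norm_denominator / total_mapped` (default per
#' ten million), the depth normalization applied to Start-Seq 5' end counts
#' and to MNase fragment-center tracks.
#'
#' @param track a `SignalTrack`.
#' @param total_mapped total mapped (non-duplicate) reads or fragments; > 0.
#' @param norm_denominator scale target (default 1e7).
#' @return The normalized track (state `"per10M"`).
#' @export
normalize_per_ten_million <- function(track, total_mapped,
                                      norm_denominator = 1e7) {
  stopifnot(total_mapped > 0)
  track_scale(track, norm_denominator / total_mapped, norm = "per10M")
}

#' Mean of replicate tracks
#'
#' Genome-wide, single-nucleotide-resolution arithmetic mean of the given
#' tracks (used to merge spike-normalized replicates per condition).
#'
#' @param tracks list of `SignalTrack`s on the same strand.
#' @return A `SignalTrack` whose value at every base is the mean across
#'   replicates (absent positions count as the default, 0).
#' @export
mean_replicate_track <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  strands <- vapply(tracks, function(t) t$strand, character(1))
  stopifnot(length(unique(strands)) == 1L)
  out <- signal_track(strand = strands[1],
                      label = paste0("mean(", length(tracks), " replicates)"),
                      norm = tracks[[1]]$norm)
  chroms <- unique(unlist(lapply(tracks, function(t) names(t$values))))
  k <- length(tracks)
  for (chrom in chroms) {
    n <- max(vapply(tracks, function(t) {
      v <- t$values[[chrom]]; if (is.null(v)) 0L else length(v)
    }, integer(1)))
    acc <- numeric(n)
    for (t in tracks) {
      v <- t$values[[chrom]]
      if (!is.null(v)) acc[seq_along(v)] <- acc[seq_along(v)] + v
    }
    out$values[[chrom]] <- acc / k
  }
  out
}

# ---------------------------------------------------------------------------
# bedGraph I/O (4 columns, 0-based half-open)

#' Read a bedGraph file into a SignalTrack
#'
#' @param path 4-column bedGraph (chrom, start, end, value; 0-based
#'   half-open). Track lines and comments (`#`) are skipped.
#' @param strand strand slot for the resulting track (`"+"`, `"-"`, `"*"`).
#' @param default default value for unwritten positions (use `NA_real_` for
#'   score tracks such as conservation, where absent bases are missing).
#' @param label track label (defaults to the file name).
#' @return A `SignalTrack`.
#' @export
read_bedgraph <- function(path, strand = "*", default = 0,
                          label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  track <- signal_track(strand = strand, label = label, default = default)
  if (!any(keep)) return(track)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop("malformed bedGraph line ", idx[which(nf != 4L)[1]], " in ", path,
         ": expected 4 fields")
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | end <= start)
  if (length(bad)) {
    stop("malformed bedGraph line ", idx[bad[1]], " in ", path)
  }
  width <- end - start
  # expand each interval to per-base positions
  pos <- rep(start, width) + sequence(width) - 1L
  val <- rep(value, width)
  chrom <- rep(m[, 1], width)
  for (cn in unique(m[, 1])) {
    sel <- chrom == cn
    track <- track_add(track, cn, pos[sel], val[sel])
  }
  track
}

#' Write a SignalTrack as a bedGraph file
#'
#' Runs of equal nonzero (non-`NA`) values are merged into intervals;
#' zero/default runs are omitted. `write_bedgraph()` then `read_bedgraph()`
#' reproduces the track on all written positions.
#'
#' @param track a `SignalTrack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in sort(names(track$values))) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values) & r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g",
                       chrom, starts[keep], ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Fragment sets (paired-end fragments as intervals)

#' Construct a fragment set
#'
#' A `FragmentSet` is a data.frame of 0-based half-open intervals
#' (`chrom`, `start`, `end`, `strand`) with bookkeeping flags recording
#' whether it has been deduplicated and length-filtered.
#'
#' @param chrom,start,end,strand parallel vectors (strand defaults to `"+"`).
#' @param deduplicated,length_filtered state flags.
#' @return A `FragmentSet` data.frame.
#' @export
fragment_set <- function(chrom = character(), start = integer(),
                         end = integer(), strand = "+",
                         deduplicated = FALSE, length_filtered = FALSE) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (n > 0) stopifnot(all(df$start < df$end))
  structure(df, deduplicated = deduplicated,
            length_filtered = length_filtered,
            class = c("FragmentSet", "data.frame"))
}

#' Read fragments from a BED file (BED3/BED6)
#' @param path BED file, 0-based half-open; column 6 (strand) used if present.
#' @return A `FragmentSet`.
#' @export
read_fragments_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  strand <- if (ncol(raw) >= 6L) raw[[6]] else "+"
  fragment_set(chrom = raw[[1]], start = as.integer(raw[[2]]),
               end = as.integer(raw[[3]]), strand = strand)
}

#' Write fragments as BED6
#' @param frags a `FragmentSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  if (nrow(frags) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d\t.\t0\t%s",
                     frags$chrom, frags$start, frags$end, frags$strand),
             path)
  invisible(path)
}

#' Remove duplicate fragments
#'
#' A duplicate is a fragment with identical (chrom, start, end) to one already
#' seen; mate strands are not consulted. Idempotent.
#'
#' @param frags a `FragmentSet`.
#' @return The deduplicated `FragmentSet`.
#' @export
dedup_fragments <- function(frags) {
  key <- paste(frags$chrom, frags$start, frags$end)
  out <- frags[!duplicated(key), , drop = FALSE]
  attr(out, "deduplicated") <- TRUE
  out
}

#' Keep fragments within an inclusive length range
#'
#' @param frags a `FragmentSet`.
#' @param len_min,len_max inclusive bounds on `end - start`.
#' @return The filtered `FragmentSet`.
#' @export
filter_fragment_lengths <- function(frags, len_min, len_max) {
  len <- frags$end - frags$start
  out <- frags[len >= len_min & len <= len_max, , drop = FALSE]
  attr(out, "length_filtered") <- TRUE
  out
}

#' Single-nucleotide fragment-center track
#'
#' Each fragment contributes +1 at its midpoint base,
#' `floor((start + end) / 2)` in 0-based coordinates (for even-length
#' fragments the downstream of the two central bases). Fragment centers
#' approximate nucleosome dyads for MNase data.
#'
#' @param frags a `FragmentSet` (length-filter beforehand for MNase use).
#' @return An unstranded `SignalTrack` whose total equals `nrow(frags)`.
#' @export
fragment_center_track <- function(frags) {
  track <- signal_track(strand = "*", label = "fragment centers")
  if (nrow(frags) == 0) return(track)
  mid <- (frags$start + frags$end) %/% 2L
  for (cn in unique(frags$chrom)) {
    sel <- frags$chrom == cn
    track <- track_add(track, cn, mid[sel], 1)
  }
  track
}

#' Transposase insertion coverage track from paired-end fragments
#'
#' Coverage over the first 9 bp of both mates of each pair (where the
#' transposase was bound): `[start, start+9)` for the plus mate and
#' `[end-9, end)` for the minus mate. With `smooth = TRUE` each 9-bp core is
#' extended 21 nt on both sides to 51 bp before accumulating.
#'
#' @param frags a `FragmentSet` of full fragments (pairs).
#' @param smooth extend each 9-bp region symmetrically to 51 bp.
#' @return An unstranded `SignalTrack`; raw total coverage is
#'   `18 * nrow(frags)`.
#' @export
atac_insertion_track <- function(frags, smooth = FALSE) {
  track <- signal_track(strand = "*", label = "insertion coverage")
  if (nrow(frags) == 0) return(track)
  core <- 9L
  ext <- if (smooth) 21L else 0L
  starts <- c(frags$start - ext, frags$end - core - ext)
  width <- core + 2L * ext
  chrom <- c(frags$chrom, frags$chrom)
  pos <- rep(starts, each = width) +
    rep.int(seq_len(width) - 1L, length(starts))
  pos <- pmax(pos, 0L)  # clip at chromosome start
  chrom <- rep(chrom, each = width)
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    track <- track_add(track, cn, pos[sel], 1)
  }
  track
}
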