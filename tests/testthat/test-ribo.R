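cfg <- pipeline_config()

test_that("P-sites sit 12 nt downstream of the footprint 5' end", {
  fr <- fragment_set("chr1", c(100L, 171L), c(130L, 201L),
                     strand = c("+", "-"))
  ps <- psite_track(fr, cfg)
  expect_equal(track_slice(ps[["+"]], "chr1", 112, 113), 1)
  expect_equal(track_slice(ps[["-"]], "chr1", 188, 189), 1)
  expect_equal(track_total(ps[["+"]]) + track_total(ps[["-"]]), 2)
})

test_that("phasing statistics match the closed-form chi-square", {
  mk <- function(frames) {
    # P-sites at offsets 0..(3n-1) downstream of anchor 1000 with the given
    # per-frame counts
    pos <- integer(0)
    val <- numeric(0)
    for (f in 0:2) {
      if (frames[f + 1] > 0) {
        pos <- c(pos, 1000L + f)
        val <- c(val, frames[f + 1])
      }
    }
    list("+" = make_track(pos, val), "-" = signal_track("-"))
  }
  pure <- phasing(mk(c(50, 0, 0)), "chr1", 1000L, "+")
  expect_equal(pure$frame0_fraction, 1)

  flat <- phasing(mk(c(100, 100, 100)), "chr1", 1000L, "+")
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p, 1)

  skew <- phasing(mk(c(180, 10, 10)), "chr1", 1000L, "+")
  expect_equal(skew$chisq, 289)
  expect_lt(skew$p, 1e-10)
  expect_equal(sum(skew$frames), skew$total)

  none <- phasing(mk(c(0, 0, 0)), "chr1", 1000L, "+")
  expect_true(is.na(none$p))
})

test_that("the used upstream ATG is the one with the highest coverage", {
  genome <- list(chr1 = paste(rep("C", 6000), collapse = ""))
  # plant two ATGs in the region between ectopic (4800) and canonical (5000)
  substr(genome$chr1, 4851, 4853) <- "ATG"
  substr(genome$chr1, 4901, 4903) <- "ATG"
  mkps <- function(pos, val) list("+" = make_track(pos, val),
                                  "-" = signal_track("-"))
  ps <- mkps(c(4860L, 4910L), c(100, 40))
  sel <- select_ectopic_atg(genome, ps, "chr1", 4800L, 5000L, "+", cfg)
  expect_equal(sel$anchor, 4850L)

  ps2 <- mkps(c(4860L, 4910L), c(40, 100))
  sel2 <- select_ectopic_atg(genome, ps2, "chr1", 4800L, 5000L, "+", cfg)
  expect_equal(sel2$anchor, 4900L)

  empty <- list(chr1 = paste(rep("C", 6000), collapse = ""))
  expect_null(select_ectopic_atg(empty, ps, "chr1", 4800L, 5000L, "+", cfg))
})

test_that("upstream ATG detection scans the sense strand only", {
  expect_true(has_upstream_atg("CCATGC"))
  expect_false(has_upstream_atg("CCCCCC"))
  expect_false(has_upstream_atg("CCCATC"))  # CAT = reverse-complement ATG
  # a minus-strand region extracted through region_sequence is already
  # reverse-complemented, so the same scan applies
  genome <- list(chr1 = "AACATAA")  # minus strand reads TTATGTT
  seq_minus <- startshift:::region_sequence(genome, "chr1", 0L, 7L, "-")
  expect_true(has_upstream_atg(seq_minus))
})

test_that("region RPKM follows the closed form and scales with depth", {
  # region: surrogate -115..-26 (90 nt) upstream of TSS 5000
  starts <- seq(4890L, 4930L, by = 5L)  # 9 fragments inside the region
  fr <- fragment_set("chr1", starts, starts + 30L)
  r <- shifted_region_rpkm(fr, 1e7, "chr1", 5000L, "+", cfg = cfg)
  expect_equal(r$length, 90)
  expect_equal(r$count, 9)
  expect_equal(r$rpkm, 10)
  r2 <- shifted_region_rpkm(fr, 2e7, "chr1", 5000L, "+", cfg = cfg)
  expect_equal(r2$rpkm, 5)
  r0 <- shifted_region_rpkm(fr[0, ], 1e7, "chr1", 5000L, "+", cfg = cfg)
  expect_equal(r0$rpkm, 0)

  # explicit ectopic TSS: region between it and canonical - 25
  re <- shifted_region_rpkm(fr, 1e7, "chr1", 5000L, "+",
                            ectopic_pos = 4800L, cfg = cfg)
  expect_equal(re$length, 175)
})

test_that("genes above 5% of the library are removed, at 5% kept", {
  counts <- c(gA = 60, gB = 50, gC = 10)
  kept <- filter_dominant_genes(counts, 1000, cfg)
  expect_equal(kept, c("gB", "gC"))
  all_small <- filter_dominant_genes(c(x = 1, y = 2), 1000, cfg)
  expect_equal(all_small, c("x", "y"))
})

test_that("cumulative coverage sums across anchors and mirrors on minus", {
  ps <- list("+" = make_track(1000:1005, c(6, 5, 4, 3, 2, 1)),
             "-" = make_track(2000:2005, c(1, 2, 3, 4, 5, 6)))
  one <- cumulative_coverage(ps, data.frame(chrom = "chr1", pos = 1000L,
                                            strand = "+"), c(0L, 5L))
  expect_equal(one$coverage, c(6, 5, 4, 3, 2, 1))
  # minus-strand anchor at 2005 reads the same values downstream
  two <- cumulative_coverage(ps, data.frame(chrom = "chr1",
                                            pos = c(1000L, 2005L),
                                            strand = c("+", "-")),
                             c(0L, 5L))
  expect_equal(two$coverage, 2 * c(6, 5, 4, 3, 2, 1))
})

test_that("planted upstream ORFs phase in KD and RNA-like reads do not", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_genes = 40, seed = 27), dir)
  truth <- sim$truth
  kd <- psite_track(read_fragments_bed(file.path(dir, "ribo_kd.bed")), cfg)
  rna <- psite_track(read_fragments_bed(file.path(dir, "rna_ctl.bed")), cfg)
  uorf <- truth[!is.na(truth$uorf_pos), ]
  expect_gt(nrow(uorf), 0)
  for (i in seq_len(nrow(uorf))) {
    ph <- phasing(kd, uorf$chrom[i], uorf$uorf_pos[i], uorf$strand[i],
                  span_codons = 20L)
    expect_lt(ph$p, 1e-6)
    expect_gt(ph$frame0_fraction, 0.6)
  }
  # pooled RNA-Seq-like control at canonical start codons: no periodicity
  f <- c(0, 0, 0)
  for (i in seq_len(nrow(truth))) {
    cds <- offset_to_position(300L, truth$tss[i], truth$strand[i])
    f <- f + phasing(rna, truth$chrom[i], cds, truth$strand[i])$frames
  }
  expect_lt(abs(f[1] / sum(f) - 1 / 3), 0.03)
})
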