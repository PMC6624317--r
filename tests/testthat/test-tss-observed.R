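cfg <- pipeline_config()

test_that("a dominant 5'-end peak relocates the observed TSS strandwise", {
  for (strand in c("+", "-")) {
    tss <- 5000L
    anno <- make_anno(tss, strand)
    pair <- make_pair(offset_to_position(50L, tss, strand), 10,
                      strand = strand)
    calls <- call_observed_tss(anno, pair, make_polII(tss), cfg)
    expect_equal(calls$observed, offset_to_position(50L, tss, strand))
    expect_equal(calls$distance, 50L)
    expect_equal(calls$source, "startseq_primary")
    expect_equal(calls$reads, 10)
  }
})

test_that("positions with fewer than five reads fall back to the annotation", {
  tss <- 5000L
  anno <- make_anno(tss)
  pair <- make_pair(tss + 300L, 4)
  calls <- call_observed_tss(anno, pair, make_polII(tss), cfg)
  expect_equal(calls$observed, tss)
  expect_equal(calls$source, "annotation_lowreads")
})

test_that("a depleted Pol II window triggers re-selection near the annotation", {
  tss <- 5000L
  anno <- make_anno(tss)
  # 50 reads far downstream where Pol II is absent; 6 reads at +30
  pair <- make_pair(c(tss + 800L, tss + 30L), c(50, 6))
  polII <- make_polII(tss, level = 10, halfwidth = 400L)
  calls <- call_observed_tss(anno, pair, polII, cfg)
  expect_equal(calls$observed, tss + 30L)
  expect_equal(calls$source, "polII_rescued")
})

test_that("missing chromosomes keep the annotation with a warning", {
  anno <- make_anno(5000L, chrom = "chrX")
  pair <- make_pair(5050L, 10)
  expect_warning(calls <- call_observed_tss(anno, pair, make_polII(5000L),
                                            cfg),
                 "chrX")
  expect_equal(calls$source, "annotation_kept")
  expect_equal(calls$observed, 5000L)
})

test_that("identical observed positions reduce to the shortest distance", {
  tss <- 5000L
  a1 <- make_anno(tss, id = "gA")
  a2 <- make_anno(tss + 270L, id = "gB")
  anno <- transcript_annotation(rbind(as.data.frame(a1), as.data.frame(a2)))
  pair <- make_pair(tss + 300L, 40)  # both transcripts call the same base
  calls <- call_observed_tss(anno, pair, make_polII(tss), cfg)
  expect_equal(nrow(calls), 2)
  red <- deduplicate_calls(calls, cfg)
  expect_equal(red$gene_id, "gB")  # distance 30 beats distance 300
})

test_that("clusters drop low-confidence members before choosing", {
  tss <- 5000L
  riken <- make_anno(tss, id = "gR", low_confidence = TRUE)
  normal <- make_anno(tss + 300L, id = "gN")
  anno <- transcript_annotation(rbind(as.data.frame(riken),
                                      as.data.frame(normal)))
  # two equal peaks: each gene resolves to the one nearest its annotation,
  # leaving two calls 150 nt apart (one cluster)
  pair <- make_pair(c(tss + 100L, tss + 250L), c(50, 50))
  polII <- make_polII(tss + 150L, halfwidth = 2000L)
  calls <- call_observed_tss(anno, pair, polII, cfg)
  expect_equal(sort(calls$observed), c(5100L, 5250L))
  red <- deduplicate_calls(calls, cfg)
  expect_equal(red$gene_id, "gN")

  # but an all-low-confidence cluster keeps its shortest-distance member
  anno2 <- transcript_annotation(rbind(
    as.data.frame(make_anno(tss, id = "gR1", low_confidence = TRUE)),
    as.data.frame(make_anno(tss + 300L, id = "gR2", low_confidence = TRUE))))
  calls2 <- call_observed_tss(anno2, pair, polII, cfg)
  red2 <- deduplicate_calls(calls2, cfg)
  expect_equal(red2$gene_id, "gR2")
})

test_that("deduplication is idempotent and separates distant calls", {
  fix <- random_observed_fixture(20, seed = 91)
  calls <- suppressWarnings(
    call_observed_tss(fix$anno, fix$start5p, fix$polII, cfg))
  red <- deduplicate_calls(calls, cfg)
  again <- deduplicate_calls(red, cfg)
  expect_identical(as.data.frame(red), as.data.frame(again))
  by_strand <- split(red$observed, red$strand)
  for (pos in by_strand) {
    if (length(pos) > 1) expect_true(all(diff(sort(pos)) > 200))
  }
})

test_that("binding classification uses the inclusive -900..+100 window", {
  for (strand in c("+", "-")) {
    tss <- 5000L
    call <- make_call(tss, strand)
    peak_at <- function(lo, hi) {
      # peak covering sense offsets lo..hi
      g <- sort(offset_to_position(c(lo, hi), tss, strand))
      data.frame(chrom = "chr1", start = g[1], end = g[2] + 1L)
    }
    expect_true(classify_nfy_bound(call, peak_at(-50L, -10L), cfg))
    expect_false(classify_nfy_bound(call, peak_at(-1200L, -950L), cfg))
    expect_true(classify_nfy_bound(call, peak_at(100L, 140L), cfg))
    expect_false(classify_nfy_bound(call, peak_at(101L, 140L), cfg))
  }
})

test_that("the caller matches an exhaustive brute-force re-implementation", {
  fix <- random_observed_fixture(50, seed = 17)
  calls <- call_observed_tss(fix$anno, fix$start5p, fix$polII, cfg)
  for (i in seq_len(nrow(fix$anno))) {
    oracle <- oracle_observed_one(fix$anno$tss[i], fix$anno$strand[i],
                                  fix$anno$chrom[i], fix$start5p, fix$polII)
    expect_identical(calls$observed[i], oracle$observed)
    expect_identical(calls$source[i], oracle$source)
  }
})
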