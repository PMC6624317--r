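test_that("bedGraph intervals expand to per-base values", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t10\t12\t3.0", path)
  tr <- read_bedgraph(path)
  expect_equal(track_slice(tr, "chr1", 9, 13), c(0, 3, 3, 0))

  writeLines(character(0), path)
  expect_equal(track_total(read_bedgraph(path)), 0)

  writeLines(c("chr1\t10\t12\t3.0", "chr1\t5\t12"), path)
  expect_error(read_bedgraph(path), "line 2")
})

test_that("bedGraph write-read round-trip is the identity on written positions", {
  set.seed(42)
  tr <- signal_track("+")
  for (chrom in c("chr1", "chr2")) {
    pos <- sort(sample(0:5000, 100))
    tr <- track_add(tr, chrom, pos, sample(c(1, 2.5, 7, 0.25), 100, TRUE))
  }
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, strand = "+")
  for (chrom in c("chr1", "chr2")) {
    expect_equal(track_slice(back, chrom, 0, 5001),
                 track_slice(tr, chrom, 0, 5001))
  }
})

test_that("per-ten-million normalization scales values and conserves ratios", {
  tr <- make_track(c(10, 20), c(5, 5))
  expect_equal(track_slice(normalize_per_ten_million(tr, 1e7),
                           "chr1", 10, 11), 5)
  expect_equal(track_slice(normalize_per_ten_million(tr, 5e6),
                           "chr1", 10, 11), 10)
  set.seed(3)
  tr2 <- make_track(sample(1000, 50), sample(10, 50, TRUE))
  total <- 3.7e6
  expect_equal(track_total(normalize_per_ten_million(tr2, total)),
               1e7 * track_total(tr2) / total)
  expect_error(normalize_per_ten_million(tr2, 0))
})

test_that("replicate means are genome-wide arithmetic means", {
  t1 <- make_track(c(5, 9), c(4, 2))
  expect_equal(track_slice(mean_replicate_track(list(t1, t1)), "chr1", 0, 10),
               track_slice(t1, "chr1", 0, 10))
  zero <- signal_track("+")
  half <- mean_replicate_track(list(zero, t1))
  expect_equal(track_slice(half, "chr1", 0, 10),
               track_slice(t1, "chr1", 0, 10) / 2)
  t2 <- make_track(0:9, rep(6, 10))
  t3 <- make_track(0:9, rep(3, 10))
  expect_equal(track_slice(mean_replicate_track(list(t2, t3)), "chr1", 0, 10),
               rep(4.5, 10))
})

test_that("fragment centers land on the midpoint base and conserve mass", {
  fr <- fragment_set("chr1", c(100, 100), c(140, 141))
  ct <- fragment_center_track(fr)
  expect_equal(track_slice(ct, "chr1", 120, 121), 2)  # even and odd length
  set.seed(5)
  starts <- sample(1000, 40)
  fr2 <- fragment_set("chr1", starts, starts + sample(100:200, 40, TRUE))
  expect_equal(track_total(fragment_center_track(fr2)), 40)
})

test_that("insertion tracks cover the first 9 bp of both mates", {
  fr <- fragment_set("chr1", 100, 200)
  raw <- atac_insertion_track(fr)
  v <- track_slice(raw, "chr1", 0, 250)
  expect_equal(which(v == 1) - 1L, c(100:108, 191:199))
  expect_equal(track_total(raw), 18)

  smooth <- atac_insertion_track(fr, smooth = TRUE)
  vs <- track_slice(smooth, "chr1", 0, 250)
  expect_true(all(vs[(79:129) + 1L] >= 1))
  expect_equal(vs[79], 0)  # position 78: outside the extended region
  expect_equal(sum(vs[1:170]), 51)  # left mate contributes 51 covered bases

  set.seed(6)
  starts <- sample(500:5000, 25)
  frn <- fragment_set("chr1", starts, starts + 180)
  expect_equal(track_total(atac_insertion_track(frn)), 18 * 25)
})

test_that("deduplication is idempotent and commutes with length filtering", {
  set.seed(7)
  starts <- sample(100, 60, replace = TRUE)
  fr <- fragment_set("chr1", starts, starts + sample(c(100, 150, 190), 60, TRUE))
  d1 <- dedup_fragments(fr)
  expect_identical(as.data.frame(dedup_fragments(d1)), as.data.frame(d1))
  a <- dedup_fragments(filter_fragment_lengths(fr, 120, 180))
  b <- filter_fragment_lengths(dedup_fragments(fr), 120, 180)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
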