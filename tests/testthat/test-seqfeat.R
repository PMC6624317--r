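test_that("CCAAT boxes are counted on both strands with overlaps", {
  expect_equal(count_ccaat("CCAATxxCCAAT"), 2L)
  expect_equal(count_ccaat("ATTGG"), 1L)
  expect_equal(count_ccaat("CCAAG"), 0L)
  expect_equal(count_ccaat("CCAATTGG"), 2L)  # overlapping sense + antisense
  expect_equal(count_ccaat(c("CCAAT", "ATTGG", "AAAAA")), c(1L, 1L, 0L))
})

test_that("CCAAT counts are reverse-complement symmetric", {
  set.seed(13)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(count_ccaat(s), count_ccaat(rc))
  }
})

test_that("initiator dinucleotides span offsets -1 and 0 on the sense strand", {
  genome <- list(chr1 = "TTTTCATTTT")
  plus <- initiator_at(genome, "chr1", 5L, "+")  # C at -1, A at 0
  expect_equal(plus$dinucleotide, "CA")
  expect_true(plus$yr)

  genome2 <- list(chr1 = "TTTTGATTTT")
  ga <- initiator_at(genome2, "chr1", 5L, "+")
  expect_equal(ga$dinucleotide, "GA")
  expect_false(ga$yr)

  # minus strand: sense -1 base is genomic tss+1; TG on the plus strand
  # reads CA on the minus strand
  genome3 <- list(chr1 = "TTTTTGTTTT")
  minus <- initiator_at(genome3, "chr1", 4L, "-")
  expect_equal(minus$dinucleotide, "CA")
  expect_true(minus$yr)
})

test_that("conservation profiles skip missing bases", {
  tr <- signal_track("*", default = NA_real_)
  tr <- track_add(tr, "chr1", c(100L, 102L), c(0.5, 0.9))
  anchors <- data.frame(chrom = "chr1", pos = 101L, strand = "+")
  prof <- conservation_profile(tr, anchors, c(-1L, 1L))
  expect_equal(unname(prof$profile), c(0.5, NaN, 0.9))
  expect_equal(unname(prof$gene_mean), 0.7)

  const <- track_add(signal_track("*"), "chr1", 90:110, 2)
  p2 <- conservation_profile(const, anchors, c(-5L, 5L))
  expect_true(all(p2$profile == 2))

  # minus-strand anchors mirror the profile
  asym <- track_add(signal_track("*", default = NA_real_), "chr1",
                    100:104, c(1, 2, 3, 4, 5))
  plus <- conservation_profile(asym, data.frame(chrom = "chr1", pos = 102L,
                                                strand = "+"), c(-2L, 2L))
  minus <- conservation_profile(asym, data.frame(chrom = "chr1", pos = 102L,
                                                 strand = "-"), c(-2L, 2L))
  expect_equal(unname(minus$profile), rev(unname(plus$profile)))
})

test_that("promoter feature rows report planted sequence elements", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_genes = 20, seed = 33), dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  truth <- sim$truth
  calls <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    make_call(truth$tss[i], truth$strand[i], truth$chrom[i],
              truth$gene_id[i])
  }))
  ect <- data.frame(gene_id = truth$gene_id[truth$shifted],
                    position = truth$ectopic_pos[truth$shifted])
  feats <- promoter_features(genome, calls, ect)
  # every canonical TSS carries the planted YR initiator
  expect_true(all(feats$initiator_yr))
  expect_true(all(feats$initiator == "CA"))
  # bound promoters carry at least the planted CCAAT box
  expect_true(all(feats$ccaat_upstream[truth$bound] >= 1))
  # ectopic TSSs carry the planted initiator too
  expect_true(all(feats$ectopic_initiator_yr[truth$shifted]))
})
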