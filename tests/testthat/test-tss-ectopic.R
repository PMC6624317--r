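cfg <- pipeline_config()

sf6 <- stats::setNames(rep(1, 6), c(paste0("ctl_", 1:3), paste0("kd_", 1:3)))
cond6 <- rep(c("ctl", "kd"), each = 3)

# six identical track pairs carrying the given (offset, count) signal
six_pairs <- function(off, ctl_val, kd_val, tss = 5000L, strand = "+") {
  pos <- offset_to_position(off, tss, strand)
  c(lapply(1:3, function(i) make_pair(pos, ctl_val, strand)),
    lapply(1:3, function(i) make_pair(pos, kd_val, strand))) |>
    stats::setNames(names(sf6))
}

test_that("bins tile -995..+994 in 199 ten-nt bins", {
  call <- make_call(5000L)
  for (case in list(c(-995L, 0L), c(-986L, 0L), c(-985L, 1L))) {
    tracks <- six_pairs(case[1], 3, 3)
    b <- bin_counts(call, tracks, cfg)
    expect_equal(nrow(b), 199)
    expect_equal(b$off_lo[1], -995L)
    expect_equal(b$off_hi[199], 994L)
    hit <- which(b$ctl_1 > 0)
    expect_equal(b$bin[hit], case[2])
  }
  # conservation: binned totals equal the track mass in the tiled region
  set.seed(23)
  off <- sample(-995:994, 60)
  tracks <- six_pairs(off, 2, 2)
  b <- bin_counts(make_call(5000L), tracks, cfg)
  expect_equal(sum(b$kd_2), 120)
})

test_that("core bins and bins nearer another TSS are excluded", {
  call <- make_call(5000L)
  other <- make_call(5000L - 120L, gene_id = "g2")
  all_calls <- rbind(call, other)
  b <- bin_counts(call, six_pairs(0L, 1, 1), cfg)
  b <- exclude_bins(b, call, all_calls, cfg)

  core_bin <- b[b$off_lo == -35L, ]  # covers -35..-26: outside the core
  expect_false(core_bin$exclude_reason %in% "core_region")
  expect_true(all(b$excluded[b$off_lo <= 24 & b$off_hi >= -25]))
  expect_equal(unique(b$exclude_reason[b$off_lo == -25L]), "core_region")

  # neighbor TSS 120 nt upstream: bin midpoint at -80 is 80 nt from its own
  # TSS but 40 nt from the neighbor
  bin80 <- b[b$off_lo == -85L, ]  # midpoint -80.5
  expect_true(bin80$excluded)
  expect_equal(bin80$exclude_reason, "nearer_other_tss")

  # without neighbors only the core region is excluded
  b2 <- exclude_bins(bin_counts(call, six_pairs(0L, 1, 1), cfg), call,
                     call, cfg)
  expect_equal(unique(b2$exclude_reason[b2$excluded]), "core_region")
  expect_equal(sum(b2$excluded), 5)  # the bins spanning offsets -25..+24
})

test_that("identical counts give zero fold change and are never selected", {
  call <- make_call(5000L)
  tracks <- six_pairs(c(-300L, -100L), c(8, 20), c(8, 20))
  b <- exclude_bins(bin_counts(call, tracks, cfg), call, call, cfg)
  b <- nb_bin_test(b, sf6, cond6)
  expect_true(all(b$log2fc == 0))
  expect_null(select_ectopic(b, call, tracks[4:6], cfg))
  expect_error(nb_bin_test(b, sf6[c(1, 4)], cond6[c(1, 4)]),
               ">= 2 replicates")
})

test_that("the ectopic base is the KD argmax, ties toward the TSS", {
  call <- make_call(5000L)
  # strong KD-only signal at -120 plus a weaker one at -115 (same bin)
  tracks <- c(lapply(1:3, function(i) make_pair(5000L, 1)),
              lapply(1:3, function(i) {
                make_pair(c(5000L - 120L, 5000L - 115L), c(30, 12))
              })) |> stats::setNames(names(sf6))
  res <- call_ectopic_tss(call, tracks, sf6, cond6, kd_level = "kd", cfg)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$offset, -120L)
  expect_equal(res$calls$shift_distance, 120L)

  # exact tie at 30 reads: -114 is closer to the TSS than -120
  tracks2 <- c(lapply(1:3, function(i) make_pair(5000L, 1)),
               lapply(1:3, function(i) {
                 make_pair(c(5000L - 120L, 5000L - 114L), c(30, 30))
               })) |> stats::setNames(names(sf6))
  res2 <- call_ectopic_tss(call, tracks2, sf6, cond6, kd_level = "kd", cfg)
  expect_equal(res2$calls$offset, -114L)
})

test_that("sliding-window maximum difference matches hand traces", {
  call <- make_call(5000L)
  flat <- make_pair(seq(4000L, 6000L), 1)
  expect_equal(sliding_max_difference(call, flat, flat, cfg = cfg), 0)

  # KD has a single spike of 15 at -115 and nothing else; control is 1/base:
  # any 10-nt window holding the spike scores 15 - 10 = 5
  kd <- make_pair(5000L - 115L, 15)
  expect_equal(sliding_max_difference(call, flat, kd, cfg = cfg), 5)
})

test_that("binding-strength sextiles are stable under monotone relabeling", {
  x <- c(5, 1, 9, 3, 7, 2)
  expect_equal(sort(chip_strength_bins(x)), 1:6)
  expect_equal(chip_strength_bins(x), chip_strength_bins(x^2 + 10))
  expect_equal(chip_strength_bins(rep(4, 12)),
               rep(1:6, each = 2))  # stable first-occurrence ranking
})

test_that("shift summaries report the median upstream distance", {
  ect <- data.frame(gene_id = c("a", "b", "c"), position = 1:3,
                    offset = c(-100L, -115L, -130L), bin = 1:3,
                    padj = 0.01, shift_distance = c(100L, 115L, 130L))
  s <- shift_summary(ect)
  expect_equal(s$median_shift, 115)
  expect_equal(s$upstream_fraction, 1)
  empty <- shift_summary(ect[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median_shift))
})

test_that("the full caller agrees with the brute-force reference", {
  set.seed(31)
  n_genes <- 20
  calls <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    make_call(3000L + (i - 1L) * 4000L,
              strand = sample(c("+", "-"), 1),
              gene_id = sprintf("g%02d", i))
  }))
  tracks <- lapply(seq_along(sf6), function(s) {
    pair <- list("+" = signal_track("+"), "-" = signal_track("-"))
    for (i in seq_len(n_genes)) {
      off <- sample(-995:994, 40)
      val <- rnbinom(40, mu = 2, size = 20) +
        ifelse(cond6[s] == "kd" & i <= 8 & off == -150L, 40L, 0L)
      # a planted KD peak for some genes, random noise everywhere
      if (cond6[s] == "kd" && i <= 8) {
        off <- c(off, -60L - 10L * i)
        val <- c(val, 35L)
      }
      keep <- val > 0
      if (!any(keep)) next
      pos <- offset_to_position(off[keep], calls$observed[i],
                                calls$strand[i])
      pair[[calls$strand[i]]] <- track_add(pair[[calls$strand[i]]],
                                           "chr1", pos, val[keep])
    }
    pair
  }) |> stats::setNames(names(sf6))

  res <- call_ectopic_tss(calls, tracks, sf6, cond6, kd_level = "kd", cfg)

  for (i in seq_len(n_genes)) {
    gi <- calls[i, ]
    m_pkg <- as.matrix(res$bins[res$bins$gene_id == gi$gene_id,
                                names(sf6), drop = FALSE])
    dimnames(m_pkg) <- list(NULL, names(sf6))
    m_oracle <- oracle_bin_counts(gi, tracks)
    expect_equal(unname(m_pkg), unname(m_oracle))

    excl <- oracle_excluded(gi, calls)
    expect_equal(res$bins$excluded[res$bins$gene_id == gi$gene_id], excl)

    sel <- oracle_select(res$bins[res$bins$gene_id == gi$gene_id, ], gi,
                         tracks[cond6 == "kd"])
    pkg <- res$calls[res$calls$gene_id == gi$gene_id, ]
    if (is.null(sel)) {
      expect_equal(nrow(pkg), 0)
    } else {
      expect_equal(pkg$offset, sel$offset)
      expect_equal(pkg$bin, sel$bin)
    }
  }
})

test_that("no ectopic call ever lands inside the +/-25 core region", {
  set.seed(57)
  for (rep in 1:3) {
    call <- make_call(5000L, gene_id = "g1")
    tracks <- lapply(seq_along(sf6), function(s) {
      off <- sample(-200:200, 120, replace = TRUE)
      val <- rnbinom(120, mu = 5, size = 5)
      if (cond6[s] == "kd") {
        # strong knockdown gains both inside the core (must be ignored)
        # and outside it (must be the call)
        off <- c(off, -18L, 10L, -40L)
        val <- c(val, 500L, 500L, 80L)
      }
      make_pair(offset_to_position(off[val > 0], 5000L, "+"), val[val > 0])
    }) |> stats::setNames(names(sf6))
    res <- call_ectopic_tss(call, tracks, sf6, cond6, kd_level = "kd", cfg)
    expect_equal(nrow(res$calls), 1)
    expect_true(all(abs(res$calls$offset) > 25))
  }
})
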