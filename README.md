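# startshift

Transcription normally initiates at a sharply defined base — the canonical
transcription start site (TSS) — inside a nucleosome-depleted promoter
region. When a promoter-bound factor that maintains this region is lost,
three linked defects can appear: a nucleosome encroaches over the canonical
TSS, initiation relocates to an ectopic site upstream, and the extended 5'
transcript can acquire an upstream open reading frame (uORF) that is
actually translated. `startshift` is an R package for detecting and
quantifying all three from standard genomics tracks, for anyone comparing a
control against a depletion/knockdown condition with base-resolution
initiation data.

## What it computes

**Observed TSS calling** — from control capped-RNA 5'-end counts
(Start-Seq): per transcript, the highest-count position within 1 kb of the
annotation or within the densest 200-nt window (whichever is closer to the
annotation), with a Pol II-coverage rescue (re-select within 250 nt when the
501-nt Pol II window around the call drops below 2/3 of the annotated
window) and an annotation fallback below 5 reads; then deduplication of
identical and clustered calls.

**Spike-anchored normalization** — 15 synthetic capped RNAs anchor two
estimators: a per-sample regression factor (least-squares slope through the
origin against the lowest-count sample; tracks are divided by it) and
median-of-ratios size factors computed on the spike matrix alone,

```
sf_s = median_i ( k_is / (prod_t k_it)^(1/m) ),
```

which feed the count test so that global initiation changes are not
normalized away.

**Ectopic initiation test** — 10-nt bins tiling offsets −995..+995 around
each observed TSS (core −25..+24 excluded, bins nearer another TSS
excluded); per bin a two-sided exact conditional negative-binomial test of
knockdown vs control totals with dispersion

```
alpha_bin = max( (v - mu * mean(1/sf)) / mu^2 ,  a0 + a1/mu )
```

(method-of-moments vs fitted trend), Benjamini–Hochberg over all retained
(gene, bin) pairs, and per-gene selection of the ectopic base as the
knockdown count argmax inside the best significant bin (padj < 0.1, positive
log2 fold change). The core exclusion guarantees every call lies more than
25 nt from the canonical TSS.

**Nucleosome encroachment** — MNase fragments filtered to 120–180 nt,
deduplicated, reduced to single-base centers, normalized per ten million;
a promoter is *encroached* when (KD + 1)/(control + 1) summed occupancy over
the TSS window reaches 1.5.

**Upstream translation** — Ribo-Seq P-sites at footprint 5' end + 12 nt;
chi-square triplet-periodicity test downstream of start codons; selection of
the used upstream ATG by 60-nt downstream P-site coverage; RPKM of the
shifted region (ectopic TSS to 25 nt upstream of the canonical TSS, with a
−115..−25 surrogate for unbound genes); a >5%-of-library dominance filter.

**Sequence features** — both-strand overlapping CCAAT-box counts, YR
initiator dinucleotides at canonical and ectopic TSSs, conservation-profile
aggregation from externally supplied per-base scores.

**Synthetic data generator** — `simulate_dataset()` writes a complete
miniature study (genome, annotation, all assays, spike table) with full
planted ground truth, so every stage above is verified by parameter
recovery. See the methods vignette (`vignettes/startshift-methods.Rmd`) for
the model, the defaults, and what the generator does not emulate.

## A worked example

```r
library(startshift)

dir <- tempfile("sim")
sim <- simulate_dataset(sim_config(n_genes = 30, seed = 7), dir)
res <- run_all(dir, file.path(dir, "report"))

res$shift
#> $n
#> [1] 8
#> $median_shift
#> [1] 110
#> $upstream_fraction
#> [1] 1

head(res$ectopic$calls, 4)
#>   gene_id position offset bin         padj shift_distance
#> 1    g002     8489   -111  88 5.817255e-13            111
#> 2    g004    21504   -105  89 2.756121e-15            105
#> 3    g006    33509   -110  88 1.763828e-12            110
#> 4    g011    63499   -100  89 3.550904e-14            100
```

This 30-gene simulation planted 9 shifted genes; the caller recovered 8 of
them (`res$shift$n`), every call upstream (`upstream_fraction = 1`), with a
median shift distance of 110 nt — the generator plants distances with median
115. `res$summary` adds the encroachment contrast (87.5% of bound shifted
promoters gained ≥1.5-fold TSS nucleosome occupancy vs 14% of bound
non-shifted ones in this run) and the fraction of shifted regions with
higher knockdown Ribo-Seq RPKM. The report directory contains the same
results as TSV tables (`observed_tss.tsv`, `ectopic_tss.tsv`,
`occupancy_change.tsv`, `ribo_regions.tsv`, `phasing_summary.tsv`,
`promoter_features.tsv`, metagene matrices, `summary.tsv`).

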