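# promstate

Promoter chromatin state classification from ChIP-seq windows.

## The problem

In compact, gene-dense genomes such as *Drosophila*, promoter chromatin
state is commonly read out from fixed windows around each transcription
start site (TSS): RNA Pol II occupancy in −250..+250, H3K4me3 and H3K27me3
in 0..+500, H3K36me3 in +500..+1500, and a +500..+1000 "gene body" window.
From these window read counts one asks, per gene:

* Is each mark **significantly enriched**? The null distributes a library's
  *N* unique reads uniformly over the mappable genome of length *G*, so a
  *w*-bp window count is Poisson with mean λ = *N·w/G*; the per-library
  threshold is the minimal count *n* with P(X ≥ *n*) ≤ 0.05.
* What is the promoter **valency** — H3K4me3-only, H3K27me3-only,
  bivalent (both), or neither?
* Is Pol II **stalled**? The stalling index SI = (promoter reads)/(gene-body
  reads); significant promoter Pol II with SI ≤ 3 is *active*, SI ≥ 5 is
  *stalled*, and insignificant Pol II is *none*.
* How does chromatin state relate to **expression**? RPKM ≥ 1 defines
  expressed genes; genes with RPKM < 0.5 in an undifferentiated-enriched
  condition but ≥ 1 in the differentiated condition are *differentiation
  genes*; significant promoter Pol II with RPKM < 1 marks *poised
  candidates*.

The package implements this whole pipeline for users who want to run it on
their own aligned reads (BED) and annotations (genePred/refFlat, BED12,
GTF), plus the supporting machinery the analysis needs: a three-step
transcript eligibility filter for overlapping genes and close TSSs,
dominant-transcript selection for multi-isoform genes, strand-aware window
derivation, duplicate capping, fragment-size estimation from the strand
peak offset, coverage tracks, TSS metaprofiles, window-based island calling
against a Poisson background, sequencing-depth saturation curves, and
RNA-seq vs microarray present/absent concordance. A synthetic-data
generator plants ground-truth chromatin states so every stage is testable
end to end without external data.

## Worked example

The calibration arithmetic on a real-scale library — 1,342,075 unique Pol
II reads over the 120,381,546-bp mappable fly genome, 500-bp windows:

```r
library(promstate)
cal <- calibrate_threshold(1342075, 500, 120381546, alpha = 0.05)
cal
#> <library_calibration> 1,342,075 reads over 120,381,546 bp, 500-bp window
#>   lambda=5.5743  alpha=0.05  threshold=11 reads (P(X>=thr)=0.02743)
round(window_pvalue(11, cal), 2)
#> [1] 0.03
```

A window with 11 reads has upper-tail probability 0.03 under the Poisson
background, so 11 is the minimal significant count at α = 0.05; 10 reads
(P = 0.058) is not significant.

A full synthetic run with planted classes:

```r
cfg <- simulation_config(seed = 42, n_genes = 2000)
ds  <- simulate_dataset(cfg, "simdata")
rep <- run_pipeline(list(
  annotation = ds$paths$annotation,
  reads = list(polII = ds$paths$reads_polII, k4 = ds$paths$reads_k4,
               k27 = ds$paths$reads_k27, k36 = ds$paths$reads_k36),
  rpkm = ds$paths$rpkm,
  genome_mappable_bp = unname(ds$chrom_sizes[[1]]),
  outdir = "out", seed = 42))
rep$quadrants[rep$quadrants$subset == "all", ]
#>    subset  valency     n total percent
#> 1:    all  k4_only   694  2000    34.7
#> 2:    all k27_only   355  2000    17.8
#> 3:    all bivalent   104  2000     5.2
#> 4:    all  neither   847  2000    42.4
```

The quadrant table counts genes per valency class among the 2,000
promoter-eligible genes; percentages are round-half-up. Per-gene calls,
stalling indices, and the differentiation/up-regulation/poised flags are in
`rep$genes` and in `out/gene_classification.tsv`. Planted classes are
recovered at ≥ 95% per class under the default generator settings
(enrichment fold 5 over a λ = 4 background; see the methods vignette).

`inst/scripts/run-pipeline.R` is a thin shell wrapper over `run_pipeline()`
driven by a YAML config.

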