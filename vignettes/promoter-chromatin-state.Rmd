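---
title: "Promoter chromatin state from window read counts: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin state from window read counts: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstate)
```

This vignette documents the statistical model behind `promstate`, the
parameters that matter, the design choices made where the procedure was
genuinely open, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## The enrichment model

A ChIP-seq library of $N$ unique reads is compared against the null in
which those reads fall uniformly over the mappable genome of length $G$.
The count of read 5' positions in a fixed window of $w$ bp is then
Poisson with mean $\lambda = N w / G$. Enrichment in a window with $n$
reads is measured by the exact upper tail $P(X \ge n)$ (computed from the
complementary Poisson CDF, never a normal approximation), and the
per-library significance threshold is the minimal $n \in \{1..99\}$ with
$P(X \ge n) \le \alpha$, default $\alpha = 0.05$:

```{r}
cal <- calibrate_threshold(1342075, 500, 120381546)
cal
```

Three choices deserve comment:

* **Mappable genome length.** The Poisson rate needs a denominator the
  input BED files do not carry. The default, 120,381,546 bp, is the summed
  length of the major fly euchromatic arms (2L, 2R, 3L, 3R, X, 4); it is a
  required, overridable configuration value, and on synthetic data it must
  be set to the synthetic chromosome length.
* **No multiple-testing correction.** Calls are per-window at
  $P < \alpha$, the convention for this style of promoter survey; the
  pipeline echoes the number of windows tested so users can judge the
  expected false-positive load themselves (with ~10,000 genes and realized
  per-window type I error of 2–3%, a few hundred false calls genome-wide).
* **Which total goes into $\lambda$.** Libraries are deduplicated (at most
  3 copies per identical `(chrom, start, end, strand)` key) before
  calibration, and the post-deduplication unique count is used. The choice
  is configurable at the calibration call; using raw totals makes
  thresholds slightly more conservative.

Because the Poisson threshold is discrete, the realized per-window type I
error sits below $\alpha$, between roughly 0.02 and 0.05 depending on
$\lambda$ — relevant when interpreting the accuracy of "unmarked" calls.

## Windows, eligibility, and the dominant transcript

All coordinates are 0-based half-open; the TSS of a minus-strand
transcript is its `tx_end`, and all window offsets run along the direction
of transcription. The windows are Pol II −250..+250, H3K4me3/H3K27me3
0..+500, gene body +500..+1000 (transcripts > 1 kb only), H3K36me3
+500..+1500 (> 1.5 kb only).

Gene-dense genomes force an eligibility filter before promoter windows can
be interpreted. The package applies three steps: (1) drop transcripts
shorter than 500 bp; (2) drop, per analysis, transcripts whose promoter
window for that analysis intersects the transcript span of a *different*
gene — an interval test that approximates diagrammatic case rules with an
order-independent criterion — and flag divergent non-overlapping pairs
whose TSSs are closer than 400 bp; (3) report survivors with per-analysis
flags. Two semantics were open and were resolved as follows: the 400-bp
TSS rule applies only to the Pol II (−250..+250) analysis, whose window
reaches upstream of the TSS into the neighbour's promoter, not to the
downstream-facing 0..+500 window; and stalling eligibility is defined as
promoter-eligible *and* Pol II-window-clean *and* TSS-clean *and* length
> 1 kb, so stalling-eligible genes are a strict subset of
promoter-eligible genes. Both choices are exercised by the test suite's
brute-force filter oracle.

Multi-isoform genes are represented by one dominant transcript per
analysis, chosen by ordered count criteria (primary window count, then a
secondary count that depends on transcript length, then transcript length,
then a seeded random draw). Where tied isoforms straddle the length
boundary that decides which secondary count applies, the
short-transcript criterion is used for the whole tied set — the original
rule is defined per transcript and silent on mixed ties; using one
criterion for the whole set keeps the comparison exchangeable. The random
tie-break seed is recorded in the run parameters, making "chosen randomly"
reproducible.

## Stalling index and Pol II classes

SI = promoter count / gene-body count. When the body count is zero and the
promoter count positive the index is $+\infty$ and, with significant
promoter enrichment, the gene is classed stalled — the limit of the rule.
Genes significant with $3 < \mathrm{SI} < 5$ fall between the active and
stalled definitions; they are kept as an explicit `intermediate` class
rather than silently dropped, so the partition
active + intermediate + stalled + none always reconciles with the
stalling-eligible gene count (genes with 0/0 windows are reported as
`NA`).

## Read-to-window assignment

Whether a window count means "reads whose 5' end falls inside" or "reads
whose fragment midpoint falls inside" is ambiguous in window-count
pipelines; both are implemented (`mode = "five_prime"` default,
`"midpoint"` with strand-aware fragment-half shift) and neither has been
verified against any external implementation. The default is the simplest
reading; the midpoint mode matches the logic of the 160-bp fragment
extension used for coverage tracks.

## Island calling and saturation

Islands are maximal runs of adjacent `window_bp` tiles (200 bp for point
marks, 400 bp for broad marks; gap 0, because gene density makes any gap
fuse neighbouring genes) whose counts pass a Poisson eligibility cutoff
(upper tail ≤ 0.2 under the background rate). An island's score is
$\sum -\ln P(\text{count} \mid \lambda)$ over member windows. The score
threshold is calibrated empirically: the same number of reads is placed
uniformly at random (seeded, 20 replicates by default) and islands are
kept when the expected number of equal-or-better null islands is at most
the E-value. A seeded empirical null was chosen over an analytic
island-score distribution: it is simpler, directly testable, and
sufficient for threshold behaviour and saturation-curve shape; numeric
identity with any particular island caller is explicitly not claimed.

Saturation analysis shuffles the library once, then calls islands in
cumulative subsamples (2.5%, 5%, …, 100%) with the E-value growing 3, 6,
…, 120, and reports the island count per fraction. On point-source
enrichment the curve rises and plateaus at the true region count. A
caveat discovered during development: for *broad* planted regions the raw
island count is non-monotone — regions fragment into several islands at
intermediate depth and merge as coverage fills in — so saturation should
be judged on the plateau, not on strict monotonicity.

## The synthetic-data generator

The generator emulates exactly the statistical structure the calibration
assumes: background reads uniform over a single synthetic chromosome
(Poisson counts in every window), plus planted per-gene states:

* `background_rate` 0.008 reads/bp per library — a ~1M-read library on a
  ~120-Mb mappable genome, giving $\lambda = 4$ per 500-bp window;
* `enrichment_fold` 5 — marked windows receive *additional* reads at five
  times the window's background expectation;
* planted stalled genes use a promoter:body total-rate ratio of 15
  (strong promoter-proximal pausing; the ratio is a parameter and the test
  suite checks that a planted ratio of 8 reproduces SI ≈ 8), active genes
  a ratio of 1.2;
* valency/Pol II/expression class proportions default to a mix resembling
  a genome-wide survey (34% H3K4me3-only, 16% H3K27me3-only, 5% bivalent,
  45% unmarked; 35% active / 15% stalled / 50% unbound; 60% expressed);
* expression: silent genes draw RPKM < 0.5, expressed ≥ 1, with planted
  differentiation (silent→expressed) and ≥2-fold up-regulated subsets, and
  microarray calls flipped to all-Absent at `false_absent_rate` 0.1.

Enriched reads derive from a *binding summit* at the window centre with a
Gaussian 25-bp spread; sequencing from either fragment end then offsets
plus- and minus-strand 5' positions by half the fragment size (160 bp
default). The summit model, rather than fragment positions uniform across
the window, is what makes the strand peak offset a sharp, recoverable
estimate of fragment size (±10 bp); with uniform placement the
cross-correlation peak is a ±window-width triangle and the estimate
wanders by ±30 bp. Window counts remain Poisson either way, so the
calibration null stays exact.

What the generator does **not** emulate: sequence content, mappability
gaps, GC bias, realistic duplicate structure, multi-chromosome genomes
(single chromosome by default — nothing in the pipeline is
chromosome-count sensitive), isoform-resolved expression, or
replicate-level microarray noise beyond the all-or-none false-absent flip.
Passing the planted-recovery tests therefore demonstrates that the
pipeline's inference is correct *under its own model assumptions*; it does
not certify performance on real libraries, where local background
variation is the dominant unmodelled effect.

## Problem sizes used in the tests

The round-trip recovery suite uses 2,000 genes (~10-Mb synthetic
chromosome, ~100k reads per library, four libraries), the scale at which
per-class recovery of at least 95% is a sharp criterion: the binding
constraint is the unmarked class, whose expected recovery is the squared
complement of the realized per-mark type I error, about 0.96 at
$\lambda = 4$. Saturation tests use 300 planted 500-bp regions over 6 Mb
at 40 subsample fractions with 5 null replicates per fraction; the oracle
suites compare 1,000 random calibrations against brute-force Poisson
summation to $10^{-12}$.

## Degenerate inputs and numerical notes

Empty libraries yield empty tracks and zero counts; windows truncated at
the chromosome start are clipped with a warning; single-strand libraries
refuse fragment-size estimation; percentages are round-half-up at the
reported precision (so 63/1304 prints 4.8 and 3796/4008 prints 95);
RPKM logs always use a pseudo-count of 1. Rerunning any stage with the
same seed is bit-reproducible, and seeded components save and restore the
caller's RNG state.

## Limitations

No input/control-library subtraction or local (sliding-window) background;
no FDR control; no isoform-resolved RPKM computation (the RPKM path
attributes reads to the dominant transcript's exon union); BED is the read
interchange format (no BAM ingestion); island calling does not implement
gapped aggregation or control normalization.
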