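---
title: "Models and methods behind h4k20dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind h4k20dyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`h4k20dyn` analyses the occupancy dynamics of H4K20 mono- and
tri-methylation together with RNA Pol II phosphoforms, chromatin
accessibility and RNA across two timepoints of erythroid maturation. This
vignette documents the models, the tunable parameters, the synthetic-data
generator that serves as the test surface, the numerical conventions, and
the design decisions taken where the design was genuinely open. It states
no empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## Signal model and region scores

A coverage track is piecewise-constant, non-negative signal over a
genome: sorted, non-overlapping half-open intervals with a value; gaps
mean zero. Tracks are canonicalised on construction (zero-value intervals
dropped, adjacent equal values merged) so equal signals have equal
representations — this is what makes end-to-end runs byte-reproducible.
Two unit systems exist: `raw_count` (library-scale) and `rpkm`. RPKM
normalisation multiplies by `1e9 / (read_bin * total_reads)` with
`read_bin = 50` bp by default, matching the bamCoverage convention, and
replicate merging is the per-base **mean** (not the sum): the mean keeps a
merged track on the same RPKM scale as a single replicate, so one set of
peak cutoffs and expression thresholds applies to both. The sum remains
available as an option.

The score of a region is `sum(value × covered bp) / region length` —
signal units per bp, with missing coverage counted as zero rather than
missing. Merged-exon ("metagene") scores pool a gene's exon intervals and
divide by the summed merged-exon length. Region scores, metagene bins and
feature counts are all computed from one exact prefix-integral of the
track, and the test suite requires agreement with dense per-base oracles
to 1e-9 on megabase windows.

Derived regions follow fixed conventions: the promoter is the
**unstranded** window TSS ± 500 bp around the strand-aware TSS (the
field's "TSS +/- 500 bp" phrasing carries no strand qualifier); the gene
body is the TSS→TES span; metagene matrices use 100 gene-body bins with
2,000 bp flanks in 50 bp bins by default (deepTools-like; integer bin
boundaries via `floor`, minus-strand rows flipped so column 1 is 5′).
Genes shorter than the bin count are dropped with a warning. Regions
running past a chromosome end are clipped and the clipped length is the
score denominator.

When a gene has several annotated transcripts (GTF input), the
longest-spanning transcript represents the gene; the source data do not
pin an isoform-collapsing rule, and a single representative keeps every
downstream per-gene quantity well defined.

## Peak calling and annotation

Peaks are maximal runs of bases with signal at or above a cutoff; runs
separated by at most `max_gap` bp are bridged and merged peaks shorter
than `min_length` bp are discarded (defaults 30 bp and 200 bp, the
`bdgpeakcall` defaults; the cutoff is data-scale-dependent and always
explicit). The summit value is the maximum signal inside the peak.
Calling is invariant to how a track is split into intervals, and a higher
cutoff yields peaks nested inside lower-cutoff regions.

Annotation assigns each peak, by its midpoint, to exactly one of
promoter (TSS −1000..+100 bp, strand-aware), TTS (TES −100..+1000 bp),
exon, intron or intergenic, in that precedence — the annotatePeaks
convention, midpoint-based for determinism. Enrichment is
`log2(observed fraction / genome fraction)` where genome fractions are
computed from the very same windows and precedence, so they partition the
genome exactly; empty categories report −Inf sentinels. Sub-categories
such as UTRs are deliberately collapsed into exon.

## Pausing index and group comparisons

The pausing-index proxy is
`PI = mean Ser5-PolII over TSS ± 500 bp / mean Ser5-PolII over TSS→TES`.
No pseudocount is used: a zero body score makes PI undefined and excludes
the gene from the split; a zero promoter score with positive body signal
is a valid PI of 0. The paused/non-paused split is taken among expressed
genes (day-7 RNA RPKM > 100) at the conventional threshold of 4, and a PI
exactly equal to 4 is non-paused, following the strict "PI > 4" reading.
Group comparisons use the Welch unequal-variance t test
(Welch–Satterthwaite degrees of freedom, two-sided); degenerate
constant-equal groups report p = 1, and group direction (increased or
decreased) is recorded with each pairwise test.

## Differential occupancy

Counts are derived from raw coverage as the rounded `sum(value × bp)`
over each feature (gene bodies for H4K20me1, promoters for H4K20me3) —
fragment-count semantics, since the pipeline consumes coverage rather
than reads. Supplying a normalised track to the counter is an error;
depth is handled by median-of-ratios size factors instead, computed over
features positive in every sample.

The test is a per-feature negative-binomial GLM with log link, known
dispersion and log size-factor offsets. With a two-group design this
separates into one Newton fit per condition, run vectorised across
features; the Wald statistic is the log2 fold change over its standard
error from the Fisher information, referred to the standard normal.
Features are called increased/decreased only when both `|log2FC| ≥ 1.5`
and BH-adjusted p < 0.05 hold, after an RNA gate (day-7 RPKM > 25)
applied **before** adjustment, so the BH set equals the tested set. No
independent filtering or fold-change shrinkage is applied; the threshold
acts on the raw MLE.

Dispersion (`Var = μ + α μ²`) is estimated per feature by the method of
moments on normalised counts, pooled across conditions, and then
moderated toward a mean–dispersion trend. Two choices here matter and
were made after measuring calibration on planted-null simulations:

- the trend is the **arithmetic mean** of raw moment estimates within
  deciles of log base mean, not a log-linear regression — regressing
  `log(α̂)` discards the many near-zero moment estimates a small-n panel
  produces and biases the trend low;
- the moderation is **information-weighted**,
  `(df·α̂ + prior_df·trend)/(df + prior_df)` with `df = n − 2` and
  `prior_df = 20`, rather than a fixed 50/50 blend. With three replicates
  per condition a fixed blend leaves so much estimator noise in α that
  the null Wald p distribution becomes visibly anti-conservative (~8–9%
  of null features below 0.05); with information weighting the gene-wise
  term gains weight exactly as replication grows, and the null p
  distribution is indistinguishable from uniform in the package's
  Kolmogorov–Smirnov checks while planted 4-fold changes are still
  recovered with ~0.9 sensitivity at near-zero empirical FDR.

One caveat is recorded as a tested approximation rather than an
invariant: jointly scaling one sample's counts and its size factor by k
leaves results *almost* unchanged — exactly so only in the Poisson limit,
because the NB working weights `μ/(1 + αμ)` move under rescaling. The
suite asserts agreement to a few percent.

## Fate mapping and summaries

Gene-level gain/loss sets come from the classified differential results;
peak-level results map to genes through the annotation precedence
(promoter, TTS, exon, body), with intergenic peaks excluded — the source
analysis reports "genes associated with" differential peaks without
stating a rule, and the annotation-based rule keeps the mapping
deterministic and auditable. The headline intersections are genes losing
gene-body H4K20me1 while gaining promoter H4K20me3 (progressive
methylation candidates) and the reverse. Percent-by-direction summaries
truncate toward zero to whole percents (7,128 decreased of 8,236
differential features reports 86), matching how such figures are printed.
RNA L2FC quantiles rank genes above RPKM 1 and split them into five
near-equal groups; the pipeline computes the RNA log2 fold change with a
0.1 RPKM pseudocount on both timepoints so silenced genes remain finite.

Ties anywhere ranks are split (deciles, L2FC quantiles) break by label,
lexicographically, so assignments are identical across runs. The
localisation classifier (TSS- vs body-enriched) uses margin 1.0 and, by
default, the 25th percentile of the supplied scores as its signal floor —
no thresholds are published for this classification, and the quartile
floor adapts to the track's scale.

## The synthetic generator

The generator is the package's study-condition statement: a 5 Mb / 200
gene "small" genome for unit tests and a 50 Mb / 2,000 gene "medium"
genome for full-scale runs, two timepoints, three replicates, six tracks
(H4K20me1, H4K20me3, Ser5 and Ser2 Pol II, ATAC, RNA). Genes are placed
without overlap, at least 2 kb apart, with log-uniform lengths of 2–50 kb
and 1–10 exons. Class fractions default to 25% active (gene-body me1 +
Pol II + RNA covarying), 30% paused (promoter Ser5 spike at an 8:1
promoter:body score ratio, promoter me3, TSS-restricted me1, RNA
expressed), 10% silent TSS-restricted me1, 10% me1 gain and 10% me1 loss
(planted |log2FC| = 2 with concordant Pol II and RNA shifts), 5%
"globin-like" (gene-body me1 collapse with promoter me3 gain at high
expression), 10% background, plus two intergenic me3 blocks per Mb.
Replicate noise is multiplicative lognormal (σ = 0.2 by default,
independently per gene, signal compartment, timepoint and replicate),
with per-track depth factors at σ/2 tied to a recorded nominal library
size so RPKM normalisation is a real inverse operation. σ = 0 produces
byte-identical replicates, which is what makes the exactness tests
(fate-map identity, mutual-exclusivity Venn) meaningful. All outputs are
pure functions of the configuration seed.

One geometric choice deserves its rationale: the paused-class Ser5 spike
is planted on the strand-aware 500 bp *upstream* of the TSS with
amplitude `(2r − 1) ×` body level. Because the PI denominator is the full
TSS→TES body, any spike placed inside the body inflates the denominator
of short genes and caps their measurable PI at roughly `length / 500` —
a 2 kb gene could never exceed PI 4 regardless of the planted ratio. The
upstream placement makes the expected measured promoter:body ratio equal
the configured `r` for every gene length, so recovery failures in tests
reflect noise, not geometry.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: read-level sampling and mappability,
fragment-size effects, nucleosome-scale structure, antibody efficiency
differences between marks, overlapping and nested genes, copy-number and
GC biases, and biological dispersion heterogeneity beyond the single
configured α. Count-level NB simulation is separate from the
coverage-level tracks precisely so the differential engine can be
calibrated against known NB truth.

## Problem sizes and runtime choices

The default test and acceptance workloads are: 1,000 random tracks for
the peak-caller oracle, one 1 Mb window for the dense scoring oracles,
the medium fixture for pausing recovery, 2,000-feature NB panels (3 vs 3)
for differential calibration, 5,000 null simulations for Welch type-I
error, and the small fixture — run twice, plus once as chained stages —
for determinism. These sizes keep a complete run in the low minutes on a
single CPU while leaving the statistical assertions comfortable margins.

## Known limitations

- The NB engine is a deliberately compact re-implementation: no
  empirical-Bayes dispersion prior beyond the trend moderation, no
  Cook's-distance outlier handling, no multi-factor designs, and no
  parity with any specific external differential tool.
- Threshold peak calling has no background model; cutoffs are explicit
  and scale-dependent.
- Annotation granularity is the representative transcript; isoform-level
  quantification and alternative TSS choice are out of scope.
- bigWig input is not read natively; tracks travel as bedGraph.
- Correlation panels default to merged replicate tracks (per-replicate
  correlation is available by scoring replicates individually).
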