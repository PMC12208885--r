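---
title: "leukotrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leukotrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

leukotrace packages the bespoke computational steps of a study design that
traces the evolution of B-cell precursor leukemia from its pre-leukemic
state across single-cell transcriptomics and tumor-normal whole-genome
sequencing. Five analysis stages are implemented — cell-hashing
demultiplexing, single-cell QC with differential-abundance testing,
transcription-factor regulon activity filtering, a somatic variant filter
battery, and RSS motif annotation of structural-variant breakends — plus
seeded synthetic-data generators that produce inputs with known ground
truth for each stage. This vignette records the models, the parameters
that matter, and the design decisions taken where the procedures left
genuine freedom.

## Hashtag demultiplexing

Cell-hashing runs pool several mice into one droplet run; each sample is
tagged with an oligo-barcoded antibody (hashtag, HTO). Demultiplexing
recovers the sample of origin per cell from the hashtag count matrix.

The background model is estimated from empty droplets: barcodes with RNA
and protein counts above 1 that the upstream cell caller did not flag as
cells, whose log10 RNA and protein totals lie within 2 median absolute
deviations of the medians of that subset, and whose mitochondrial read
fraction is below 0.25. Per hashtag $p$, the ambient background is
summarized by the mean $\mu_p$ and sample standard deviation $\sigma_p$ of
$\log(1+x)$ counts over these empties ($\sigma_p$ floored at $10^{-8}$),
and cell signals are standardized as

$$s_{cp} = \frac{\log(1+x_{cp}) - \mu_p}{\sigma_p}.$$

No isotype-control denoising or technical-noise regression is applied;
the standardization is deliberately the plain ambient z-score.

Cells with at least one detected hashtag (raw count ≥ 1) are
over-clustered with k-means into $K = N + \binom{N}{2} + 1$ clusters for
$N$ hashtags (one cluster per singlet identity, one per doublet pair, one
background), with 100 random restarts. The cluster with the lowest mean
scaled signal is taken as background; a normal is fit to its pooled scaled
values by the method of moments and the positivity cutoff is its 99th
percentile $\hat\mu + 2.326348\,\hat\sigma$, clamped into $[3, 5]$. A cell
is positive for a hashtag when its scaled signal strictly exceeds the
cutoff; exactly one positive gives a singlet call, two or more a doublet,
none a negative. Only singlets feed downstream analysis.

Design points that the procedure description left open, decided here:

* **MAD constant.** "Median absolute deviance" is implemented as the raw
  median of absolute deviations (no 1.4826 normal-consistency constant),
  computed on log10 totals because count totals are heavy-tailed.
* **One pooled cutoff.** The normal is fit to all hashtag dimensions of
  the background cluster pooled, giving a single global cutoff rather
  than per-hashtag cutoffs — one background cluster, one cutoff.
* **Clamp, not re-fit.** A 99th percentile outside $[3, 5]$ is clamped to
  the nearest bound; the fit is not repeated.
* **Background-cluster summary.** "Lowest signal" is the mean over all
  member cells and all hashtags, the simplest scalar summary.

## Single-cell QC and differential abundance

Genes are kept when present (count > 0) in strictly more than 10 cells;
cells are kept by mitochondrial fraction, total counts, and detected-gene
bounds. The procedures report per-experiment ranges rather than single
values; the defaults here sit at the permissive end of each range
(`max_mito` 0.01, counts 500–30,000, genes 400–6,000) and are all
configurable. Because removing cells can drop genes below the prevalence
threshold (and vice versa), the two masks are recomputed and reapplied
until stable — this makes filtering idempotent, at the cost of possibly
removing slightly more than a single pass would. Per-criterion removal
counts refer to the first pass.

Normalization divides each cell by a size factor and applies `log1p`. The
default estimator is library size over the median library size; pool-based
estimators (e.g. scran's) plug in either as a supplied factor vector or as
a function. Clusters dominated by low-quality cells are flagged when their
mean per-cell fraction of counts in a housekeeping (ribosomal) gene set
falls strictly below 0.1; flagging is a report, removal is the caller's
decision.

Differential abundance between genotypes is a per-cluster Pearson
chi-squared test (df = 1) on the 2×2 table of cluster membership versus
genotype, without Yates continuity correction — cell-level counts are
large, and small expected counts are flagged (< 5) rather than corrected.
Raw p-values are reported; any multiple-testing adjustment across clusters
is left to the caller. Note that the asymptotic chi-squared p-value and an
exact permutation p-value agree only at large cell counts; at a total of
60 cells the discreteness of the permutation null dominates.

Upstream embedding steps (HVG selection, PCA, neighbor graphs, Leiden,
UMAP, batch correction) are standard and pluggable; this module consumes
cluster labels, it does not produce them.

## Regulon activity discovery and filtering

A regulon is a transcription factor with a putative target gene set.
The contribution implemented here is the sampling/stability/R² wrapper
around discovery, not the discovery machinery itself: the reference
backend defines targets as genes whose Pearson correlation with the TF
reaches `r_min` (default 0.3) across a cell-type-balanced sample, after a
uniform pseudocount jitter in (−0.01, 0.01) is added to every matrix entry
so constant genes acquire defined near-zero correlations. Regulons with
fewer than 10 targets are dropped. Any other discovery backend can be
swapped in through the `backend` argument of `stability_filter()`.

Per-cell activity is an AUCell-style rank-based recovery score: genes are
ranked per cell (descending, average ranks for ties) and the score is the
area under the step curve of target recovery within the top `q = 0.05`
fraction of ranks, normalized so targets occupying the very top ranks give
1. Scores therefore lie in $[0, 1]$ and are invariant to any strictly
monotone transform of a cell's expression values. For $m$ targets
scattered uniformly among $G$ genes the expected score has the closed form
$\frac{m\,T(T+1)/(2G)}{m(m+1)/2 + m(T-m)}$ with $T = \lfloor qG \rfloor$,
which the tests use as an oracle.

Two filters follow:

1. **Train-test stability.** Ten balanced 70:30 train-test splits,
   stratified by cell type. Regulons are discovered on the train half,
   both halves are scored, and the per-cell-type mean-score vector of the
   train half is correlated (Pearson) with that of the test half. The
   procedure names the test but not the paired quantities; the
   train-versus-test pairing is this package's reading, recorded as such.
   A TF is retained when discovered in at least half the splits with a
   median p ≤ 0.001. Splits resample the balanced set each time.
2. **Cell-type discriminability.** On the full dataset's scores, 100
   repetitions each sample 500 cells per type (with replacement when a
   type is short) and evaluate the one-way model score ~ cell type;
   $R^2 = 1 - SSE/SST$ is computed from group means (identical to
   `summary(lm(...))$r.squared`, which a unit test cross-checks). Regulons
   with mean $R^2 < 0.5$ are discarded. Under an iid null,
   $E[R^2] \approx (k-1)/(n-1)$, far below the threshold.

The final regulon set is re-discovered on the full balanced sample
restricted to the stability-retained TFs, then scored on the whole
dataset — one final set, as the procedure implies. Retained regulons can
be projected onto new populations (`project_scores()`), guarded by a
minimum target-overlap fraction (default 0.8) with the new gene universe.

## Somatic variant filtering

Tumor-normal calls are filtered by pure, vectorized clause batteries whose
verdicts name every failed clause (no short-circuiting) and treat missing
fields as unevaluable — conservative and auditable, never PASS.

* Mutect2-style SNVs/indels: NALOD > 0; TLOD ≥ 10; tumor allele fraction
  ≥ 0.05 **or** ≥ 3 alt reads (inclusive or); zero alt reads in the
  normal; alt evidence on both strands (≥ 1 read each, operationalizing
  "no evident strand bias"); median alt base quality > 30; median alt
  mapping quality ≥ 60.
* Strelka-style records: the caller's own FILTER must be exactly PASS.
* The two passing lists merge by union, deduplicated on
  (chrom, pos, ref, alt) with caller provenance kept; records sharing a
  locus and alt but disagreeing on ref indicate un-normalized input and
  raise an error. Left-alignment and multiallelic splitting are assumed
  upstream.
* SVs: caller PASS, both paired- and split-read support (≥ 1 each), and
  ≥ 5 supporting reads in total — "at least 5 paired and/or split reads"
  is read as the sum, with both kinds separately required.
* CNVs: integer copy number 0, 1, or ≥ 3, and segment length
  ≥ 10,000 bp (1-based inclusive).
* Coding selection keeps HIGH and MODERATE predicted impact.

Recurrence matrices count, per gene and variant category, the samples
carrying that category; SV deletions/duplications and CNV losses/gains
fold into shared deletion/duplication categories before counting, and a
driver-gene list can fix row order for oncoprint-style display. The
caller's own FILTER column is not additionally required for Mutect2-style
records — only the custom clauses above are applied.

## RSS motif annotation at SV breakends

Recombination signal sequences (RSS) — the consensus heptamer CACAGTG and
nonamer ACAAAAACC — mark RAG recombinase targets; their presence at SV
breakpoints suggests RAG-mediated rearrangement. Each breakend at 1-based
position $p$ yields the window $[\max(0, p-1-f), \min(L, p+f))$ in 0-based
half-open coordinates with $f = 100$: up to 201 bp, the breakend base
included, clipped at contig edges. The 201 bp reading (rather than 200)
is a documented choice. Windows are scanned for exact motif occurrences
on both strands — minus-strand hits are reported in plus-strand
coordinates — with overlaps all reported, case-insensitive matching, and
`N` matching nothing. Matching is delegated to Biostrings; the test suite
checks it against a naive position-by-position oracle. Palindromic motifs
report distinct hits per strand. Larger motif collections (e.g. a
cryptic-RSS screen's top list) are supplied as a motif file, not vendored;
the default set carries only the two consensus sequences. Hits are joined
back onto their SVs together with affected-gene annotations; SVs without
hits stay in the output with empty hit lists.

## Synthetic data: what it emulates, and what it does not

Each generator is seeded and returns ground truth alongside the data.

* **Droplets**: ambient hashtag counts are rounded `expm1` of normal draws
  on the log1p scale (mean 2, sd 0.5 by default), matching the scale the
  demultiplexer standardizes on; positive hashtags are shifted up by
  `signal_shift` (default 8 ambient SDs — a cleanly separated run);
  doublets carry two full-signal hashtags. Not emulated: sequencing-depth
  variation between droplets, antibody aggregates, or correlated ambient
  composition — so passing recovery tests demonstrate correctness of the
  assignment machinery, not robustness to every failure mode of real runs.
* **Expression**: targets are generated as $r\,\mathrm{TF} + \varepsilon$
  with the noise variance chosen so the population target–TF Pearson
  correlation equals $r$ exactly; TF modules can be elevated in chosen
  cell types (default shift 3 on the lognorm scale over noise sd 1).
  Counts are derived by `round(expm1(·))`. Not emulated: dropout,
  library-size variation, or overlapping regulatory programs unless
  declared.
* **Variants**: records carry every field the filters consume, with each
  clause drawn from its passing or failing side at a configurable
  probability; where clauses interact through shared read counts the
  realized fractions are approximate, but truth verdicts are recomputed
  per record by brute-force clause evaluation, so labels are exact by
  construction.
* **Breakend genomes**: iid A/C/G/T background at a stated GC fraction
  (default 0.42) with motifs written at exact offsets, reverse-complemented
  for minus-strand plants. Background occurrences of a motif can arise by
  chance; recovery tests therefore check containment of the planted truth,
  and the empty-truth case first verifies the background is motif-free.

## Seeds, determinism and problem sizes

A single root seed fans out to per-stage streams via a fixed arithmetic
derivation (`derive_seed()`), so each stage is independently reproducible
and full-pipeline runs are byte-identical under a fixed seed — including
the k-means restart stream and the discovery jitter. The test suite
exercises the stages at the sizes the procedures name where those are
stated (6 hashtags × 300 singlets/tag with 5,000 empties; 10 splits at
70:30; 100 R² repetitions at 500 cells/type; 5 types × 500 cells with 10
planted and 10 decoy regulons over 10 root seeds; 1,000 records per
variant type; 50 random 10 kb windows with 22 motifs), and at smaller
sizes for unit-level properties.

## Known limitations

* The demultiplexer fits one pooled background normal; strongly
  hashtag-specific background shapes would argue for per-hashtag fits.
* The QC fixpoint iteration can remove slightly more cells/genes than the
  single-pass variant used by common toolkits.
* The correlation discovery backend is intentionally simple; it stands in
  for heavier co-expression machinery behind a stable interface and should
  not be mistaken for a full gene-regulatory-network method.
* Variant filtering assumes normalized, annotated inputs; no realignment,
  annotation, or purity modeling is performed.
* RSS scanning is exact-match only — no position-weight matrices, RIC
  scores, or 12/23 spacer-rule pairing.
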