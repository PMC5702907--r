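---
title: "Methods: tissue-contrast multi-omics of the cereal seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-contrast multi-omics of the cereal seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcontrast)
```

# The scientific problem

The dry mature cereal seed contains two filial compartments of very
different ploidy, origin and fate: the diploid embryo (about 2% of
whole-seed dry weight in rice) and the triploid endosperm (the remaining
98%). `seedcontrast` implements an end-to-end contrast of these two tissues
across three molecular layers — label-free shotgun proteome, microarray
transcriptome (long-lived stored mRNAs) and GC-MS primary metabolome — plus
the downstream integration, enrichment and storage-protein phylogeny
stages. Every statistic is on the endosperm-to-embryo axis: a positive log2
ratio means endosperm-favored, negative embryo-favored.

# Models and procedures per layer

## Proteome: XIC rollup and z-score contrast

Peptide-ion quantification tables (one extracted-ion-current area per ion,
tissue and biological replicate) pass through:

1. **Specificity filter** — ions matching more than one protein are
   discarded; shared peptides cannot be attributed.
2. **Reproducibility filter** — per tissue, an ion must be detected in at
   least 2 of the 3 biological replicates. The filter is per tissue: an ion
   can be quantifiable in the embryo and discarded in the endosperm.
3. **Within-sample summation** — repeated detections of one ion in one
   sample are summed.
4. **Rollup** — protein abundance per (tissue, replicate) is the sum of its
   ions' areas, then log2. Missing replicates are excluded from tissue
   means, never imputed as zero: dropout in label-free data is
   abundance-dependent, and a zero would bias ratios far more than a
   smaller-n mean.

For proteins quantified in both tissues the contrast is
$r_i = \log_2 \bar A_{i,\mathrm{end}} - \log_2 \bar A_{i,\mathrm{emb}}$,
where $\bar A$ averages the raw-scale replicate abundances (the
`"mean-of-log"` alternative averages per-replicate log2 abundances and is
exposed via `ratio_mode`; it differs by the usual arithmetic/geometric-mean
gap and is provided because either reading of "average abundance" is
defensible).

Two classifications are computed on $r$:

* **Favored classes** (`favored_by_median()`): within the positive ratios,
  features *strictly above* the median of the positive ratios are
  endosperm-favored; symmetrically for negative ratios. The median is taken
  per sign class because the source analysis quotes two separate thresholds
  (one positive, one negative); a single all-ratio median cannot produce
  two cutoffs. Strict inequality implements "superior to the median", so
  an all-equal sign class classifies nothing.
* **z-score differential** (`zscore_differential()`):
  $z_i = (r_i - \bar r)/s_r$ with $s_r$ the sample standard deviation of
  *all* common-protein ratios (not any later integration subset — the
  differential analysis precedes pairing), $p_i = 2\Phi(-|z_i|)$,
  significant at $p < 0.05$. This is a descriptive outlier analysis, valid
  insofar as the ratio distribution is near normal; `shapiro_normality()`
  (Royston approximation via `stats::shapiro.test`) is reported as a
  diagnostic and never used as a gate.

## Transcriptome: presence calls, Bonferroni t-tests, strong filter

Normalized probe matrices arrive with per-sample P/M/A detection calls;
neither MAS5 nor GC-RMA is re-implemented. A probe is detected in a tissue
when at least 2 of 3 replicate calls are P (selectable: `all`, `any`).
Marginal calls count as absent — "ambiguous" probes are removed. The
default 2-of-3 rule mirrors the proteome reproducibility rule; the source
text does not state its consensus rule, so the choice is documented here
and switchable.

Differential expression uses the equal-variance two-sample t-test
(pooled variance, $df = n_1 + n_2 - 2$) across the detection universe, with
Bonferroni control at 0.01; the family size $m$ counts only testable probes
(non-zero pooled variance) that survived detection filtering, because
filtering precedes testing. The "strong" filter then keeps DE probes whose
mean intensity in the favored tissue strictly exceeds the median of the
per-(probe, tissue) mean intensities over the whole detected universe; the
global (not per-tissue) median is used because the filter expresses "high
expression on the array", not "high relative to its own tissue".

## Metabolome: dry-weight normalization and Student-t/FDR

GC-MS peak areas come per mg dry weight. Per-seed abundance is
`per_mg * tissue_fraction * seed_dw_mg` with the 0.02/0.98 embryo/endosperm
fractions; `seed_dw_mg` defaults to 20 mg (a typical dehulled rice
caryopsis) and cancels from every ratio. The conversion shifts all log2
ratios by exactly $\log_2(0.98/0.02) = 5.615$ — the package treats this
identity as a tested invariant. Tissue-specific calls use the same 2-of-3
detection rule. Differential accumulation on common metabolites uses the
Student (equal-variance) t-test with Benjamini–Hochberg FDR at 0.05.
BH was chosen because the source names only "False Discovery Rate" for
metabolites while naming Yekutieli explicitly for enrichment; the BY
variant is available through `fdr_method = "BY"`.

## Integration: unique probe-set/protein pairs

Protein isoforms (`OsNNgNNNNN.K`) are collapsed to loci, keeping the more
abundant isoform when two are quantified (the source's 673→672 step implies
one collision but not its resolution; abundance is the least arbitrary
tie-break). Candidate probes are restricted to those detected in both
tissues; loci matched by more than one candidate probe are *removed*, not
arbitrated — "unique pairs" — and probes left mapping to several retained
loci are removed for the same reason. The result is a bijection; pairing
re-run on its own output is a fixed point. Concordance is the Pearson r of
the two ratio vectors plus sign-quadrant counts (exact zeros are counted
`on_axis`, in no quadrant).

## Enrichment: hypergeometric with Benjamini–Yekutieli

Over-representation of a study set against a configurable background uses
the exact upper-tail hypergeometric probability, evaluated as a sum of
log-space binomial coefficients for numerical stability at genome scale,
BY-adjusted across terms. BY is used (rather than BH) because overlapping
terms create arbitrary dependence. Terms with zero study hits are not
tested and do not enter the family size — standard over-representation
practice, switchable with `test_zero_hit` since the reference web tool's
behaviour is unknowable.

## Phylogeny: BLOSUM62 distances and neighbor joining

From a gapped alignment, pairwise similarity sums BLOSUM62 over columns
where both sequences carry residues (gap columns are ignored; no gap
penalty is stated by the source, so none is invented). The transform
$d_{ij} = 1 - 2 S_{ij} / (S_{ii} + S_{jj})$, clamped below at 0, maps
self-similarity to 0 and is the package's documented choice — the source
names only "BLOSUM62 matrix", so no published-figure topology is treated
as a ground truth. Classical neighbor joining minimizes
$Q_{ij} = (r-2) d_{ij} - R_i - R_j$ with lowest-index tie-breaking for
determinism; negative branch lengths are clamped to zero with the deficit
recorded. Trees are `ape::phylo` objects; the Newick writer is
hand-rolled and round-trips through `ape::read.tree` in the tests. The NG
(asparagine–glycine) cleavage-site scan reports 1-based positions of the
conserved glutelin precursor processing motif, overlapping matches
included.

# The synthetic-data generator

Because the study's raw deposits are not consumable at desk scale, every
pipeline input is drawn from a stated synthetic world (`omics_scenario()`):

* a common feature core with log2-scale Gaussian tissue effects
  (`tissue_effect_sd`, default 2.5 — matching the several-log2 spread of
  the published protein ratio table), split half-and-half between tissues;
* tissue-specific features that are entirely absent from the other tissue;
* three biological replicates per tissue with multiplicative log-normal
  noise (`noise_sd` = 0.5 log2 units, a ~40% CV typical of label-free
  replicates);
* per-replicate dropout (default 0.1) and, for the proteome,
  zero-truncated-Poisson peptide-ion multiplicity (mean 15, the study's
  ions-per-protein ratio) with a 5% shared-ion rate;
* default feature counts mirror the published proteome partition
  (673 common / 1426 / 113); the metabolome scenario used by the pipeline
  mirrors 117 / 6 / 1.

Ground truth is always emitted as a sidecar table so recovery tests assert
against planted memberships and effects, never against re-inference. All
generators restore the caller's RNG state and are bitwise-deterministic
given `rng_seed`.

What the generator does **not** emulate: raw spectra and chromatograms,
retention-time structure, probe-level summarization artifacts,
between-array normalization error, compositional effects, or correlated
(batch) noise. A green recovery test therefore establishes that the
*statistical pipeline* is correct under its stated assumptions, not that
those assumptions hold for any particular instrument run.

# Numerical choices and degenerate inputs

* Significance defaults: 0.05 (proteins, metabolites, enrichment), 0.01
  (transcripts).
* Zero pooled variance: probes/metabolites are flagged untestable and
  leave the multiple-testing family rather than producing p = 0 or NaN.
* Zero ratio variance: `zscore_differential()` refuses (degenerate input);
  `concordance()` reports quadrants with `r = NA` and a warning.
* Non-positive tissue means are excluded from ratio computation with a
  warning (log undefined).
* A sequence pair with no jointly gap-free column has no defined distance
  and raises an error rather than returning an arbitrary value.
* The Bonferroni-null expectation: with $m$ tests at level $\alpha/m$, the
  expected null discovery count is $\approx \alpha$ per matrix — the suite
  asserts this scale (a published-derived sketch suggesting
  $\alpha \times m$ conflates adjusted and raw testing).
* Config files round-trip through JSON (no YAML parser is part of the
  supported stack).

# Known limitations

* The per-sign-class median reading of the favored classification is one
  of two defensible readings of the source text; the published 76/267
  counts match neither reading exactly, so favored *counts* are not
  acceptance-tested, only the rule's behaviour.
* The z-score population (all common ratios vs the paired subset) is
  likewise ambiguous in the source; the full set is used.
* The BLOSUM62 score-to-distance transform of the original tool is
  unstated; tree topology from the published figure is therefore not a
  test target, only internal consistency (additivity, round-trips,
  recovery of simulated families).
* Enrichment treats annotations as flat sets; no ontology propagation.
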