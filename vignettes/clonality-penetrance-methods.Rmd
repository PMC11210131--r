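---
title: "Methods: clonality and penetrance analysis of cis-regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality and penetrance analysis of cis-regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `clonalCRE`. The package analyses chromatin-accessibility
heterogeneity in a disease-stage patient cohort profiled by ATAC-seq: it
scores the clonality and penetrance of every accessible cis-regulatory
element (CRE), tests differential accessibility against a cohort-resampling
null, selects and clusters dynamically engaged CREs, quantifies enhancer RNA
(eRNA) at their non-exonic bases, links them to target genes through
chromatin loops, and ranks candidate genes by lineage-restricted dependency.

```{r setup}
library(clonalCRE)
```

## Coordinate and overlap conventions

All user-facing coordinates are BED-style 0-based half-open `[start, end)`;
the conversion to the 1-based closed convention of
`GenomicRanges`/`IRanges` happens in one internal helper. "Overlap" means
at least 1 bp everywhere: two book-ended intervals (`[100,200)`,
`[200,300)`) do not overlap and never merge. Master-list construction is a
single-linkage union-merge of all sample peaks under this rule; the merge
rule used by the original study is not published, and union-merge is the
conventional default. The minimum-overlap threshold is a parameter of
`build_master_list()`.

A fragment that spans two disjoint master regions increments both counts:
the counting is per-region coverage, not fragment assignment.

## Clonality Index

For a sample with total mapped reads $N$, a peak of width $w$ carrying $c$
reads has

$$\mathrm{Nscore} = \frac{(c / w) \cdot 10^{-6} \cdot 10^{-3}}{N}.$$

Present master regions are ranked by decreasing Nscore, and the Clonality
Index is the percentile bin $\mathrm{CI} = \lceil 100\,r / n \rceil$ for
rank $r$ among $n$ present regions: 1 is the most enriched percentile, 100
the least, and absent regions score 0. Three conventions are deliberate:

* CI is computed over each sample's *present* repertoire only, not over the
  whole master list — the score is a within-sample ranking.
* Ties share the bin of their minimum rank.
* The multiplicative constants in the Nscore cancel in the ranking; CI is
  invariant to any positive rescaling, which the tests assert.

The verbatim orientation (1 = highest enrichment) is the default;
`clonality_index(..., invert = TRUE)` reports `101 - CI` for present
regions when an "activity increases with the score" reading is preferred.

## Penetrance Index and composition

The Penetrance Index of a master region is the number of in-scope samples
with at least one overlapping peak, read from master-list provenance. Over a
32-sample cohort it ranges from 1 (private) to 32. Penetrance bands are
private (PI = 1), low (2–14) and high (> 14); the 14 cut-off is the
configurable `low_cut` parameter. The observed/expected analysis between two
groups compares, per PI value, the count of group-A-detected regions against
proportional allocation of the pooled (A plus B, with multiplicity) per-PI
counts by A's overall detected-region share; PI values with expected count 0
are reported as missing rather than 0, so downstream plots do not conflate
"no data" with "depletion".

## Differential accessibility and the resampling null

Counts are normalized by TMM (trimmed mean of M-values), implemented
in-package following the standard definition: reference sample closest to
the mean 75th-percentile count fraction, two-sided trimming of 30% of
M-values and 5% of A-values, inverse-asymptotic-variance weights, factors
rescaled to geometric mean 1. The test suite cross-checks the factors
against the independent `edgeR` implementation. Normalized values are
$\log_2$ counts per million over effective library sizes with a 0.5
pseudocount (the pseudocount avoids $-\infty$ at zero counts with minimal
bias).

The differential engine used by the original study is not named; the
package default is a per-region Welch two-sample $t$ test on the
log-normalized values with Benjamini–Hochberg adjustment, called at
|log2 fold change| > 0.7 and a configurable FDR. Welch was chosen over a
pooled-variance test because per-region variances differ substantially
between stages in overdispersed count data; dispersion shrinkage across
regions is deliberately out of scope. Degenerate regions with zero variance
in both groups get $p = 1$ when the means agree and $p \to 0$ otherwise.

The expected-by-chance analysis re-runs the same test on pseudo-cohorts:
labels drawn without replacement into two disjoint groups whose sizes match
the true comparison, 100 iterations by default, seed mandatory. The
observed/expected ratio is the true-label significant count over the mean
null count. On the synthetic design with planted stage effects this ratio
exceeds 10 by a wide margin; on exchangeable data it concentrates near 1
*when the significance rule is per-region stable* — with a BH gate the
significant count under the null is heavy-tailed (the step-up threshold
cascades), so the calibration test disables the FDR gate and checks the
ratio under a pure fold-change rule.

## Dynamic-CRE selection and clustering

The selection rule keeps regions that are (a) penetrant across the disease
stages (PI over onset, remission and relapse samples at least
`min_pi_disease`), (b) near-silent in healthy samples (detected in at most
`max_healthy_ci_fraction` of them), and (c) dynamic: the per-stage median
clonal activity changes by at least `min_ci_delta` CI bins between some
pair of stages. Criterion (c) is evaluated on an activity scale (0 when
absent, `101 - CI` when present): on the raw CI scale an absent region (0)
and a top-enriched region (CI 1) are one bin apart, and exactly the most
dynamic regions would fail the delta. The published selection criteria
behind the reported dynamic-CRE catalogue are unstated, so the defaults
(`min_pi_disease = 15`, `max_healthy_ci_fraction = 1/3`,
`min_ci_delta = 20`) are documented stand-ins, and tightening any of them
provably never enlarges the selection.

Clustering follows the conventional heatmap default, which the original
analysis (an "unsupervised clustering heatmap") does not pin down: rows
z-scaled to mean 0, sd 1; Euclidean distance; Ward linkage (`ward.D2`); the
tree cut at `k = 4` clusters and at 2 for the clade split. Constant rows are
dropped with a warning rather than producing NaN distances. Cluster labels
from a tree cut are arbitrary, so when stage groups are supplied the
clusters are relabeled by decreasing disease activity (mean z-score in
onset+relapse minus healthy+remission); C1 and C2 then name the
disease-active clade, matching the convention used downstream by the
enhancer-tier gate.

The chromatin module score of a region set for one unit (sample or cell) is
the mean of the unit's within-column z-scores over the set, minus the same
mean over a size-matched background set drawn with a fixed seed.
Within-unit z-scoring makes the score invariant to adding a constant to a
unit's column and yields exactly 0 on constant input; z-scoring per region
would satisfy neither property.

## eRNA, tiers, loops, targets, dependency

eRNA is counted over the *non-exonic* bases of each CRE: the exon union is
subtracted at base level, and a fragment counts when it overlaps at least
1 bp of the remaining eligible intervals (a fragment touching only exonic
bases of the CRE is not counted; whether the original analysis discarded
partially exonic fragments is unstated). Productive CREs are those called
up in the disease group by the same Welch/BH machinery applied to log2-CPM
eRNA counts.

Enhancer tiers are a deterministic function of cluster label and >= 1 bp
overlap flags against three external catalogues (eRNA annotation,
super-enhancers, cell-line peaks): a CRE in the disease-active clusters (C1
or C2) shared with the cell line is a candidate productive enhancer;
otherwise the super-enhancer flag, then the eRNA flag, decides the tier.

Loops are classified promoter–promoter, promoter–CRE or CRE–CRE by whether
each anchor overlaps a promoter window (TSS ± 5 kb, reusing the promoter
annotation window; the loop-classification window of the original study is
unstated); an anchor overlapping both a promoter and a CRE counts as
promoter, so the three classes partition all loops. Loop distance is
measured between anchor midpoints (resolution-independent), histogrammed
with a dedicated < 50 kb bin; trans-chromosomal loops are classified but
excluded from the histogram. Target assignment prefers loop evidence — one
anchor on the CRE, the other on a gene's promoter window, an anchor
spanning two promoters linking both genes — and falls back to proximity
(|CRE midpoint − TSS| ≤ 10 kb). When both exist for a pair, the loop link
is reported.

Dependency ranking sorts each gene's cell lines ascending by score (lower =
more dependent) and counts lineage-of-interest lines in the most-dependent
set. Both reported variants of the set size are implemented — a fixed
`top_k` (e.g. 100 lines) and a `top_fraction` (default 0.10) — because the
source analysis describes both; ties at the boundary are included rather
than arbitrarily broken, and missing scores drop a line from that gene's
ranking only.

## The synthetic cohort generator

No generative model is published for the cohort, so the generator's
distributional choices are explicit stand-ins with the statistical structure
the analysis assumes:

* **Design**: 32 samples — 6 healthy, 11 onset, 7 remission, 8 relapse —
  matching the study design the package targets.
* **Counts**: negative binomial per present (peak, sample) cell,
  `nb_mean = 50`, `nb_dispersion = 0.3` (variance $= \mu + 0.3\mu^2$), a
  typical overdispersion for ATAC-seq peak counts at moderate depth;
  detected peaks are clamped to a minimum count of 1 (a detected peak with
  zero reads is a contradiction), which biases moments negligibly at these
  means. Absent peaks are omitted from the sample's repertoire.
* **Penetrance architecture**: shared high-penetrance "core" peaks
  (carriers above the low-penetrance cut), onset-restricted private/low
  peaks sized so that the realized fraction of onset-detected peaks in the
  private/low band matches `frac_private_low_onset = 0.6`, per-stage peaks
  for the other stages, and healthy-silent "dynamic" peaks in four activity
  patterns (onset+relapse, onset-only, relapse-only, flat across disease).
  The onset+relapse pattern carries the planted fold-4 accessibility effect
  and is the "dynamic productive" truth set for recovery tests.
* **Placement**: peaks are uniform over two synthetic chromosomes (12 and
  8 Mb), rejection-sampled to at least 1 bp gaps so that the master-list
  merge of the fixture is unambiguous; a `promoter_fraction` of 20% is
  placed within 5 kb of a synthetic TSS.
* **RNA fragments**: fixed-length 75 bp intervals (paired ends collapsed),
  exonic background everywhere, baseline non-exonic CRE coverage, and a
  fold-4 elevation at flagged productive CREs in onset samples.
* **Loops and dependency**: planted CRE-to-promoter loops plus random
  promoter–promoter and CRE–CRE loops; a genes-by-cell-lines Gaussian score
  matrix with an 11-line "B-ALL" lineage whose scores for planted essential
  genes are shifted downward.

Everything is driven by a single integer seed; identical configuration and
seed give byte-identical outputs, which the tests assert file-by-file.

What the generator does *not* emulate: GC and mappability bias, fragment
insert-size structure, duplicate and mitochondrial artifacts, single-cell
sparsity, genuine biological covariance between neighbouring peaks, or the
~150,000-region scale of a real cohort master list. Passing tests therefore
demonstrate that the statistical machinery recovers what it is designed to
recover under its own model assumptions — not that those assumptions hold
in any particular real data set, and headline counts from the deposited
cohort (master-list size, differential-region counts, catalogue sizes) are
not reproducible at this scale.

## Problem sizes and determinism

The default synthetic design uses roughly 3,900 master regions across 32
samples; test fixtures use a few hundred regions and 8 samples; the
calibration suite uses 2,000 regions by 16 samples with up to 200 null
replicates and 100 resampling iterations. These sizes were chosen so the
properties under test (type-I error within ±0.02 of nominal, ≥ 90% planted
recovery, oracle equivalence over ≥ 100 random fixtures) are measured with
comfortable Monte-Carlo margins while the whole suite stays fast.

All stochastic stages take explicit seeds (`resampling_expected()` refuses
to run without one). `run_pipeline()` with identical configuration writes
byte-identical artifacts, and stages fail with the failing stage's name.

## Known limitations

* The selection thresholds, clustering algorithm, differential engine,
  promoter window for loops, and master-list merge rule are all reasoned
  defaults for choices the source analysis leaves unstated; each is a
  visible, documented parameter rather than a hidden constant.
* CI percentile binning over small repertoires (< 100 peaks) cannot fill
  all 100 bins; bins are exact only when the repertoire size is a multiple
  of 100.
* `penetrance_oe()` is descriptive; no confidence interval is attached to
  the O/E ratio.
* The eRNA counting is strand-unaware and does not assemble transcription
  units; bidirectional eRNA calling is out of scope.
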