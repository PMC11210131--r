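# clonalCRE

Dissecting chromatin-accessibility heterogeneity across disease stages in
ATAC-seq patient cohorts.

## The problem

In B-cell precursor acute lymphoblastic leukemia (BCP-ALL), the repertoire of
accessible cis-regulatory elements (CREs) is rewired as patients move through
healthy, onset, remission and relapse states. Two questions drive the
analysis this package implements:

1. **How clonal and how shared is each regulatory element?** For every region
   of a cohort-wide master peak list, each sample gets a *Clonality Index*
   (CI) and the cohort gets a *Penetrance Index* (PI) per region.
2. **Which elements are dynamically engaged by disease, and what do they
   regulate?** Highly penetrant, healthy-silent, dynamic CREs are selected,
   clustered on normalized accessibility, tested for enhancer-RNA (eRNA)
   productivity, tied to target genes through promoter-capture Hi-C loops,
   and their target genes ranked by lineage-restricted CRISPR dependency.

## The scores

For one sample with total mapped reads *N*, a peak of width *w* covered by
*c* reads has enrichment

```
Nscore = ((c / w) * 1e-6) * 1e-3 / N
```

Present peaks are ranked from highest to lowest Nscore and the ordered list
is divided into percentiles: **CI = ceil(100 * rank / n_present)**, from 1
(highest enrichment) to 100 (lowest); master regions absent from the sample
get CI 0. CI is a pure rank statistic — invariant to the constants above and
to sequencing depth.

**PI** is the number of cohort samples sharing the region (>= 1 bp overlap
between a sample peak and the master region), from 1 (private) to the cohort
size. Regions with PI in 1..14 are the private/low-penetrance band.

Downstream stages use standard machinery: TMM scale factors with log2-CPM
values, per-region Welch tests with Benjamini-Hochberg correction at
|logFC| > 0.7, an expected-by-chance analysis that re-runs the differential
test on 100 resampled pseudo-cohorts, Ward clustering of z-scaled
accessibility into clusters C1..C4, base-level exon subtraction for eRNA
counting, >= 1 bp anchor overlap for loop classification, and a
top-k / top-fraction most-dependent-lines count for dependency screens.

Everything runs against a bundled synthetic-cohort generator
(negative-binomial counts, configurable penetrance architecture, planted
effects), so the full pipeline is testable offline.

## Worked example

```r
library(clonalCRE)

pp <- run_pipeline(pipeline_config(cohort_config(seed = 7L),
                                   n_iter = 20L, seed = 7L))
summary(pp)
#> Pipeline summary
#>   master regions: 3870
#>   differential healthy vs onset: 985 significant (|logFC| > 0.7 , FDR < 0.05 )
#>   observed/expected by resampling: 19700
#>   dynamic CREs selected: 267
#>   cluster sizes: C1=113, C2=40, C3=48, C4=66
#>   productive CREs (up at onset): 50
#>   candidate productive enhancers: 52
#>   loop classes: promoter-promoter=26, promoter-CRE=53, CRE-CRE=16
#>   loop-linked genes: 32
```

The synthetic cohort has 32 samples (6 healthy / 11 onset / 7 remission / 8
relapse) and ~3,900 master regions. The healthy-vs-onset comparison finds
orders of magnitude more differential regions than label-resampled
pseudo-cohorts (observed/expected ratio 19,700 here; the planted stage
effects are strong). Of the selected dynamic CREs, the 50 generator-planted
onset+relapse-active productive elements all land in cluster C1, are all
called significantly more eRNA-productive at onset, and enter the candidate
productive-enhancer tier with loop-supported target genes.

The clinical-summary utility reproduces its worked examples from a cohort
table:

```r
s <- summarize_cohort(example_cohort_table(), group_col = "group")
subset(s$categorical, variable == "sex" & level == "M" & group == "newly_diagnosed")
#>              group variable level  n pct
#> 32 newly_diagnosed      sex     M 21  70
subset(s$numeric, variable == "age_at_relapse")
#>      group       variable mean median min max
#> 1 relapsed age_at_relapse 11.7   10.5   5  23
```

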