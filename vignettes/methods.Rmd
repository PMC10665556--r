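---
title: "Methods: models, parameters and design choices"
author: "atriskimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriskimmune)
```

# Scope

`atriskimmune` implements a cross-sectional, three-group immune-profiling
analysis for studies of individuals at risk for seropositive rheumatoid
arthritis. The three participant groups are ACPA-negative controls
(`ctrl`), ACPA-positive individuals without inflammatory arthritis
(`at_risk`), and ACPA-positive early RA (`early_ra`). Four analysis arms
share these group labels:

1. **Methylome**: differential methylation in sorted B, memory-T and
   naive-T cells across two independent cohorts, with replication,
   gene/pathway mapping and group classification.
2. **Tetramer**: frequencies of CD4+ T cells specific for citrullinated
   antigens, enumerated by HLA class II tetramer staining after magnetic
   enrichment.
3. **Landscape**: an aligned-cluster phenotype landscape over six surface
   markers (CD45RA, CD38, CCR4, CCR6, CXCR3, CCR7), with tetramer-positive
   cells overlaid.
4. **Serology**: a multiplexed bead-array panel of autoantibody levels with
   positivity calling and covariate-adjusted group models.

A fifth module reproduces baseline-table statistics from printed
counts and summaries, and a synthetic-data generator emulates all input
kinds with planted, recoverable group effects. Raw-array preprocessing
(IDAT parsing, normalisation, probe QC) is out of scope; QC is represented
by a generic probe blacklist filter.

# Methylome arm

## The DML definition

Each probe carries a methylation fraction $\beta \in [0,1]$. For a group
pair, a probe is a *differentially methylated locus* (DML) when a Welch
two-sample $t$-test on $\beta$ gives $p < 0.05$ **and** the absolute
difference of group mean $\beta$ exceeds 0.1. No multiple-testing
correction is applied to this per-locus screen — deliberately so: the
two-gate rule (nominal significance plus a biologically meaningful effect
size) is the operative filter, and downstream replication across an
independent cohort supplies the error control. Both gates are parameters
(`alpha`, `delta_beta`).

The test is computed on $\beta$ values, not M-values, because the
effect-size gate is defined in $\beta$ units; M-values
($\log_2 \beta/(1-\beta)$, after clipping $\beta$ into
$[10^{-3}, 1-10^{-3}]$) are used for embeddings, clustering and
classification, where their better variance behaviour matters.

With three groups, two modes are available. `any_pair` (default) runs all
three pairwise comparisons and calls a probe if any pair passes both
gates; `pairwise` restricts to one stated pair. Both are exposed because
"differences among three groups" admits either reading; the any-pair union
is the default as it reduces to pairwise calling when only two groups are
present.

Missing values are handled pairwise-complete per probe; probes with zero
pooled variance are flagged degenerate, given a missing p-value, and never
called.

## Replication and gene mapping

Cohort-level DML sets are compared by an exact upper-tail hypergeometric
test on the filtered-probe universe: with universe $N$, cohort sets of
sizes $K$ and $n$, and overlap $m$,
$p = \sum_{i=m}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$.
The union of the cohort sets feeds gene mapping.

A probe supports a gene promoter when it lies within the strand-oriented
window $[\mathrm{TSS}-2500, \mathrm{TSS}+500]$ bp, and the gene body when
it lies inside the annotated gene interval; promoter assignment wins.
Design choices here: both window ends are closed (the source convention
is unstated; closed ends make the boundary cases deterministic and are
asserted in tests), coordinates are 1-based, and minus-strand windows are
reflected in genomic space. Genes with at least one supporting probe are
differentially methylated genes (DMG). Pathway over-representation of the
DMG list against user-supplied gene sets (GMT) uses the same
hypergeometric form on a gene universe with Benjamini–Hochberg FDR across
sets, flagged at FDR < 0.1.

## Classification

One-vs-one random forests distinguish each group pair on the previously
called DML (M-values). Samples are split 70/30 stratified by group; a
small grid — trees $\in \{200, 500\}$, `mtry` $\in \{\sqrt p, p/3\}$ — is
tuned by stratified 10-fold cross-validation on the training split, and
held-out accuracy is reported. A grid search was part of the original
design but its contents were not; this grid covers the two
hyperparameters that matter for random forests at these dimensions. The
top 10% of features by Gini importance are exported for combined-model
PCA. All stochastic steps (split, folds, forests) derive from one seed
and the report is reproducible bit-for-bit.

# Tetramer arm

With 1% of cells reserved before magnetic enrichment to estimate the total
CD4 count, the frequency of tetramer-positive cells per million CD4+ T
cells is

$$F = \frac{10^6 \times \text{tmr}^+\text{ events (enriched)}}
           {100 \times \text{CD4}^+\text{ cells (pre-enrichment 1\%)}}.$$

The combined citrullinated-antigen frequency is the **sum** over the four
cit specificities (aggrecan, CILP, vimentin/fibrinogen, alpha-enolase),
excluding the influenza control. A mean variant is available
(`combine = "mean"`); the sum is the default because the quantity of
interest is the total burden of cit-reactive cells, and the choice does
not affect rank-based group tests when all subjects have the same antigen
set. Subjects with a non-positive pre-enrichment count are excluded (the
frequency is undefined), not imputed.

Group comparisons use the two-sided unpaired Wilcoxon rank-sum test:
exact p-values for small untied samples, normal approximation with tie
correction otherwise (the `stats::wilcox.test` policy). All-tied input
returns p = 1 with a warning rather than an error.

# Landscape arm

Raw intensities are arcsinh-transformed with $a = 0$, $b = 1/150$
(cofactor 150, the conventional scale for fluorescence cytometry). Each
subject's events — total CD4 plus the appended tetramer-positive events,
matching the concatenated-file layout used upstream — are clustered with
a phenograph-family algorithm: a k-nearest-neighbour graph (default
$k = 30$) partitioned by Louvain modularity. A `resolution` parameter
(default 1) controls granularity; a k-means fallback covers very small
event tables. Clustering is deterministic under the supplied seed.

Each individual cluster with frequency above 1% of the subject's events
is profiled as a six-marker z-score vector against the subject's own
total CD4 mean and SD in transformed space. Tetramer-positive events are
included in that reference by default: at their realistic abundance
(well under 1% of a full-size event table) their influence is negligible,
and a flag (`exclude_tmr_from_reference`) removes them for down-sampled
data where it is not. Profiles are metaclustered across subjects with
Euclidean distance and Ward linkage (`ward.D2`), and the dendrogram is
cut into a configured number of aligned clusters (ACs; default 10 — a
typical landscape granularity for six markers, not an algorithmic
constant). Per subject, AC occupancy fractions are computed separately
for total CD4 and for each tetramer antigen; subjects contribute to an
antigen's statistics only with at least 8 antigen-specific events.
Events whose individual cluster fell below the 1% floor remain
unassigned, so assigned fractions sum to at most 1 (exactly 1 before the
floor — an asserted invariant). AC fractions are compared between groups
per AC with the same Wilcoxon test as the tetramer arm.

# Serology arm

An antibody is **positive** for a subject when its MFI is at or above the
control-group mean plus 3 control SDs for that antigen (boundary
inclusive, matching the `>=` form of the rule). Similar peptides are
aggregated by summing MFI within antigen groups (e.g. cit-clusterin,
cit-fibrinogen, cit-histone-H4, cit-CILP), and positive antibodies are
counted per subject overall and per group.

Group contrasts (control vs at-risk; at-risk vs early RA) are modeled
with age, sex and smoking (ever/never) as covariates: linear regression
for levels, logistic for single-antigen positivity, Poisson for counts
(with the Pearson dispersion statistic reported so overdispersion is
visible). Levels are modeled as $\log(\mathrm{MFI}+1)$ by default — MFI
is strongly right-skewed — with `log_mfi = FALSE` available to check
robustness on the raw scale. The FDR family is all targets within one
outcome type and one pairwise comparison, adjusted by Benjamini–Hochberg;
the family definition is configurable because no canonical one exists for
this design. Logistic fits with complete separation are flagged; the
coefficient is stabilised by a small ridge penalty and the Wald p is
reported as missing rather than fabricated. Analyses can be re-fit within
*04:01-carriage strata, and the CILP T-cell/antibody relationship is
assessed by two-sided Spearman correlation.

# Baseline cohort statistics

Dichotomous baseline traits are compared with Pearson chi-squared on the
2×2 counts **without** continuity correction, df = 1; continuous traits
with a two-sided t-test reconstructed from printed means, SDs and group
sizes (Welch by default, pooled available). The no-correction choice is
what reproduces printed baseline p-values from printed counts, verified
exactly in the test suite; some published cells (e.g. one sex comparison)
are not reproducible from the printed margins under any standard 2×2 test
and are not asserted. Fisher's exact test is provided as a utility for
sparse tables, not as the default.

# The synthetic-data generator

The generator is first-class, tested code: it defines the operating
conditions under which every arm's recovery properties are asserted.

* **Methylation**: per-probe baseline means are drawn from a U-shaped
  beta distribution (mimicking the bimodal methylated/unmethylated
  landscape of array data); within-group noise is logit-normal with a
  beta-scale SD (default 0.03, a typical within-group probe SD; real
  studies do not publish a canonical value, so it is an explicit config
  knob), which keeps values strictly inside (0,1). Planted probes shift
  the designated group's mean by `delta_beta_effect` towards 0.5, and a
  configurable fraction of planted loci is shared between cohorts.
  Default sample sizes follow the study design this emulates
  (cohort 1: 21/20/5 per group; cohort 2: 31/36/17), with the probe count
  scaled to 5000 so the full pipeline runs in seconds.
* **Cytometry**: events are a Gaussian mixture in arcsinh space over five
  phenotype archetypes (naive-like, Th1, Th2, Th17, Th17.1), mapped back
  to raw intensities; per-subject mixing proportions get Dirichlet
  jitter. Tetramer-positive counts are Poisson with mean implied by the
  configured per-million frequency and the subject's pre-enrichment CD4
  count, and are appended to the event table. The default enrichment
  matrix plants a CILP-specific expansion in the at-risk group and a flat
  influenza control; a skew record redirects at-risk CILP-specific events
  into the Th17.1-like component. The total-CD4 table is down-sampled
  (default 2000 events/subject) while tetramer counts stay realistic,
  mirroring real enriched-fraction data in which tetramer events are not
  subsampled.
* **Serology**: control MFI is log-normal per antigen; affected groups
  multiply MFI by configured antigen-group effects (defaults: modest
  cit-clusterin/fibrinogen/histone-H4 elevation at-risk, larger and
  broader elevations including cit-CILP in early RA). The 41-antigen
  panel (27 citrullinated, 14 native, ten CILP peptides) uses synthetic
  placeholder peptide identities with the real group structure.
  Covariates are drawn with the group imbalances of the published
  baseline table (age means/SDs, sex, smoking, *04:01 rates), so
  covariate adjustment is meaningful.

What the generator does **not** emulate: probe-level array artefacts and
batch effects, spectral spillover and doublets in cytometry, plate
effects and non-specific binding in serology, and any longitudinal
structure. Passing recovery tests therefore demonstrate correctness of
the statistical machinery under clean planted effects, not robustness to
real-data artefacts.

# Numerical and reproducibility choices

* One global seed fans out to per-stage child seeds through a stable
  string hash (`stage_seed`), so any stage re-run alone reproduces its
  output; all generator output is byte-identical under a fixed seed.
* Welch tests across probes use a vectorised row-wise implementation
  (means/variances via row operations, Welch–Satterthwaite df), asserted
  equal to a per-locus `t.test` loop on random matrices.
* Ward metaclustering uses `hclust(method = "ward.D2")` on Euclidean
  distances and is asserted against an independent Lance–Williams
  implementation on small profile sets.
* Ties in rank tests follow the `wilcox.test` policy; exact enumeration
  is asserted against permutation oracles for small samples.
* Degenerate inputs (zero-variance probes, all-tied groups, constant
  correlation vectors, zero-variance control antigens, empty strata) are
  flagged or skipped with messages, never silently dropped.

Problem sizes in the test and acceptance runs (5000-probe default,
300–2000 events per subject, 20-seed landscape replicates, 500-replicate
serology null) were chosen so the whole suite completes in a few minutes
on one CPU while leaving every planted-effect margin wide.

# Known limitations

* The per-locus screen is intentionally uncorrected; interpretation
  leans on cross-cohort replication, and single-cohort DML counts should
  be read as screening output.
* Louvain community detection at default resolution over-partitions
  diffuse clouds; the aligned-cluster step absorbs this, but individual
  cluster counts per subject are not biologically meaningful on their
  own.
* The ridge fallback under logistic separation yields an estimate but no
  valid p-value; separated antigens must be interpreted via the count or
  level models.
* AC biological naming (Th17.1 etc.) is user annotation; the package
  assigns only numeric AC identities.
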