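---
title: "Methods: integrative methylome-transcriptome-miRNAome analysis with triomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylome-transcriptome-miRNAome analysis with triomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`triomix` links three molecular layers measured on the same animals —
per-CpG RRBS methylation calls, gene-level mRNA counts, and miRNA
counts — for pairwise tissue comparisons. This vignette explains the
statistical models, the coordinate and threshold conventions, the
design decisions that were genuinely open, and what the synthetic
benchmark does and does not demonstrate.

## Data containers

`MethylationSet` extends `RangedSummarizedExperiment` with two integer
assays, `coverage` and `methylated`, over width-1 CpG cytosine
positions (1-based, strand kept; symmetric CpGs are *not* destranded —
merging strands is lossy and nothing downstream requires it).
`CountSet` wraps a single non-negative integer `counts` assay. Both
demand a `group` column in `colData`; validity methods enforce
`methylated <= coverage`, site uniqueness and integer counts at
construction, so downstream code never re-checks. All parsers are
strict: a malformed cell, a duplicate site or a sample missing from the
sample sheet aborts with the offending row named. The only place
0-based coordinates appear is BED export (`start = pos - 1`).

## Differential methylation

Two-group comparisons are named "A vs B" and every signed quantity is
A minus B; "hyper" always means hypermethylated in the first-named
group. Group methylation levels are coverage-weighted pooled
percentages, `100 * sum(m) / sum(n)`.

The per-site test depends on the design:

* one sample per group (or `poolReplicates = TRUE`): two-sided Fisher
  exact test on the pooled methylated/unmethylated × group table. The
  implementation enumerates the conditional hypergeometric
  distribution per margin set, summing probabilities no greater than
  the observed one with the customary `1 + 1e-7` relative tolerance.
* replicated groups: likelihood-ratio test of a group effect in the
  binomial logistic model of per-sample proportions. With a group-only
  covariate the MLEs are the group-pooled proportions, so the LRT
  statistic has a closed form; we compute it vectorised across sites
  and refer it to a 1-df chi-square. Equivalence with
  `glm(family = binomial)` plus `anova(test = "LRT")` is asserted in
  the test suite. The model does not absorb between-replicate
  overdispersion; the 25-point effect-size filter is what keeps null
  sites out in practice, and the null calibration benchmark measures
  exactly this joint behaviour.

Sites where a group has zero total coverage are reported untestable and
excluded. Multiplicity is handled with Benjamini–Hochberg (`p.adjust`);
a site is a DMS when `|diff| >= minDiff` (default 25 percentage points)
and `q < maxQ` (default 0.01). Both defaults are exposed because the
two natural q cutoffs (0.01 and 0.05) are both in circulation; the
stricter one is the package default.

Coverage filtering (default: every sample ≥ 10×, and at most that
sample's 99.9th coverage percentile, a PCR-duplicate guard) is applied
before testing; the defaults are standard RRBS practice rather than a
statistically derived quantity and are configurable.

## Differential expression

One NB engine serves mRNA and miRNA tables; no miRNA-specific
normalisation is applied. Size factors are median-of-ratios against the
geometric-mean reference (features with a zero anywhere are excluded
from the reference; if none survive, a positive-subset median is used).
Dispersion is per-feature method-of-moments on normalised counts,
`alpha = max(1e-8, (s2 - mu) / mu^2)`, with `s2` the within-group
pooled variance — deliberately simple and bias-transparent at n = 4 per
group. The Wald statistic is the moderated log2 fold change
(pseudocount 0.5 on each group mean, which bounds the statistic for
zero groups) over its delta-method SE with
`Var(mean_g) = (mean_g + alpha * mean_g^2) / n_g`. There is no fold
change shrinkage and no outlier refitting: the test stays a documented,
reproducible NB Wald, and its operating characteristics are established
by simulation rather than inherited from a reference tool.

Expression tiers rank features by mean normalised count: Q1 = bottom
quartile (`floor(n/4)` features), Q3 = top quartile, Q2 = the
interquartile half. "Medium" is read as the middle two quartiles since
the top and bottom quartiles are explicitly the high/low classes. Ties
break by feature identifier so the partition is deterministic. Tiers
are computed per comparison (over the union of the two groups'
samples); computing them over all samples jointly is a one-line change
and deliberately not a hidden default.

## Gene regions

Promoter = TSS1500 ∪ 5′UTR, where TSS1500 is the 1,500 bp *strictly*
upstream of the TSS — exclusive of the TSS base, which begins the 5′UTR
when annotated, so the two pieces never double-count. Gene body =
transcribed span minus the 5′UTR (the 3′UTR stays inside the body),
partitioned into exon and intron by the collapsed exon union.
Multi-transcript genes collapse to exon/UTR unions with the single
5′-most TSS, matching the gene-level counting used downstream. A CpG
overlapping several genes is assigned to all of them — dropping or
nearest-TSS tie-breaks would silently hide signal — while the
feature-distribution summary collapses to one class per site with
priority promoter > exon > intron so fractions sum to one. Region
assignment ignores the CpG's own strand: regions are defined by the
gene's strand.

The per-gene interval subtractions are pooled into a single
`IRanges::setdiff` call by shifting each gene into its own integer
coordinate block; a conventional per-gene path covers genomes too large
for the blocked arithmetic. Both paths are checked against a
plain-arithmetic brute-force scan on randomised gene models.

## Integration

Each DMS is paired with every overlapping gene region (exon/intron
collapse to `gene_body`; intergenic sites pair with nothing). The
expression side of a pair is the difference of group mean normalised
counts on the count scale — not log — so stratum means are directly
interpretable as expression-unit shifts. Strata are expression tier ×
region × methylation direction; each row reports CpG and distinct-gene
counts, mean methylation difference, mean expression difference, and
the Spearman correlation of the per-pair (methylation difference,
expression difference) with its significance. The pair-level reading —
as opposed to correlating within genes across samples — is what
reproduces a table whose rows carry one correlation per stratum
together with pair counts. Spearman is applied unconditionally; no
normality gating is performed (a rank statistic needs none).

Spearman rho is the Pearson correlation of average ranks. Two-sided
p-values are exact by full enumeration over the n! rank permutations
for n ≤ 7 (5,040 permutations, cached; enumeration at n = 8..10 costs
8!–10! evaluations per call, which the pair volumes of the integration
stage cannot afford, and the t approximation is already adequate
there). For n > 7, `t = rho * sqrt((n-2)/(1-rho^2))` on n − 2 df.
Constant vectors yield NA rather than a fabricated value.

Methylation-dependent genes: promoter class = at least one promoter DMS
whose direction opposes a significant expression change (hyper with
down, hypo with up; `padj < 0.05`, `|log2FC| >= 1`); body class = a
body DMS whose direction matches. A gene appears once per list however
many CpGs qualify (the CpGs are still counted), labelled
hypermeth/hypometh/mixed. Cross-comparison analysis maps each gene to
its exact membership pattern with per-comparison direction labels.

## miRNA layer

Target prediction is a deliberately transparent stand-in for external
consensus predictors: a (miRNA, gene) pair is emitted when the reverse
complement of the miRNA seed (nt 2–8, the canonical 7mer-m8 site)
occurs in the gene's 3′UTR supplied 5′→3′. U/T are interchangeable;
anything outside ACGTU is an error. A user-supplied target map bypasses
prediction entirely. Pairs are retained when Spearman r < −0.9 across
the comparison's samples *and* the target is DE.

Chains require, for a miRNA: (i) ≥ 1 promoter DMS (miRNA promoters
default to the TSS1500 window alone, since miRNA genes rarely carry
annotated 5′UTRs); (ii) the miRNA is DE; (iii) the per-sample mean
promoter-DMS methylation percentage correlates negatively with the
miRNA's normalised expression; (iv) ≥ 1 target link with negative
correlation. Chains report *all* negative-correlation DE-target links
and flag the r < −0.9 subset separately — observed chains in real data
legitimately include anti-correlations between −0.7 and −0.9, and
hiding them behind the retention cutoff would misstate the evidence.

## The synthetic benchmark

`simulationConfig()` defaults define the study conditions every
calibration and recovery number refers to: a toy chromosome with 200
three-exon genes (150 bp 5′UTR) and 20 single-exon miRNA genes; 3
promoter + 5 body CpGs per gene, 4 CpGs per miRNA promoter, 320
intergenic CpGs (~2,000 sites); two groups of 4 samples (a 4 vs 3
variant mirrors a dropped replicate); NB coverage with mean 30× (size
50); beta-binomial methylation with precision 30 so the replicated test
sees realistic overdispersion; 15% planted DMSs with 40-point shifts;
15% planted DE genes at |log2FC| = 2 over log-normal baselines (median
100, sdlog 1) with gene-wise dispersions around 0.05; 15
promoter-coupled genes; one cascade with 6 targets. Planted fractions
were fixed at design time by power analysis so that both planted and
null classes remain well populated at this problem size; replicate
counts in the benchmarks (500 null, 200 recovery, 100 cascade-null)
are the package's chosen problem sizes.

Three structural choices matter for what the benchmark can show:

* Randomly planted DMSs are spread over feature classes with weights
  emulating the distribution observed in real RRBS comparisons
  (promoter 0.04, exon 0.08, intron 0.44, intergenic 0.44) rather than
  uniformly over CpGs — promoters are CpG-dense but harbour few DMSs,
  and a uniform plant would overstate promoter-class false discovery.
* Promoter-coupled genes draw a variable shift (30–55 points) and an
  expression response proportional to it (|log2FC| 1.2–4.0, sign
  opposite to the methylation direction, scaled by
  `couplingStrength`). A fixed shift would make the planted
  methylation difference nearly constant across pairs and rank
  correlations undefined in practice; the proportional response is
  what lets stratum-level Spearman carry signal.
* Cascades run through a shared per-sample latent factor (group offset
  2, noise sd 0.5): methylation rises with the group offset, the miRNA
  loads at −1.0 and targets at +0.7 on the latent factor with tight NB
  noise (dispersion 0.02). Means alone would anti-correlate the
  *groups* but not the *samples*; the latent factor is required for
  sample-level rank correlations to cross the −0.9 retention
  threshold. Planted miRNA differential expression outside cascades is
  off by default so cascade benchmarks have a clean null.

The generator is deterministic under its seed; annotation, truth plan,
methylome, expression and sequences consume separate derived streams so
replicate studies can hold the genome and truth fixed while
re-simulating data. Truth tables record every planted effect exactly
once, and `evaluateAgainstTruth()` scores sensitivity and empirical FDR
per class.

What passing the benchmark does *not* show: the generator has no
batch or library-preparation effects, no genuine genome sequence (CpG
placement is uniform within regions, no CpG islands), no
transcript-level structure, no partially methylated domains, no
correlated neighbouring CpGs, and its miRNA targeting is exact seed
complementarity. Recovery rates measured here are therefore an upper
bound on behaviour under idealised conditions, not an estimate of
performance on tissue data.

## Numerical conventions

Fisher p-values use the `1 + 1e-7` relative tolerance when comparing
table probabilities (the convention of the standard implementation);
the log-likelihood terms of the methylation LRT use `0 * log(0) = 0`
and the statistic is floored at 0; BH is `stats::p.adjust`; tier ties
break by feature id; all pipeline TSVs are written with 15 significant
digits and deterministic row orderings so repeated runs are
byte-identical. Degenerate inputs (empty strata, constant correlation
vectors, zero-coverage groups, empty target maps) produce explicit NA
or empty results, never silent drops — except where a contract says
otherwise (pairs whose gene has no expression record are dropped *and
counted* in an attribute).

## Known limitations

Differentially methylated *regions* (tiles) are out of scope — the unit
of analysis is the single CpG. The replicated methylation test is
anticonservative under strong overdispersion, mitigated but not removed
by the effect-size filter; a beta-binomial test would be the natural
extension. The NB Wald has no shrinkage, so low-count fold changes are
noisy (visible in the simulation at baselines below ~20 counts). Seed
matching ignores thermodynamics, conservation and 3′-supplementary
pairing, and will not reproduce consensus-predictor target sets.
Multi-group designs are handled as independent pairwise comparisons.
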