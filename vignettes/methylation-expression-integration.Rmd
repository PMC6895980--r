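---
title: "Integrating CpG methylation with gene expression in a tumor-normal cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating CpG methylation with gene expression in a tumor-normal cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

## The problem

Gonadotroph nonfunctioning pituitary adenomas (NFPAs) show widespread
aberrant CpG methylation, but most differentially methylated positions
(DMPs) have no measurable consequence for transcription. The question this
package addresses is the integrative one: *which* aberrantly methylated
CpGs are coupled to the expression of their annotated gene, where do those
CpGs sit (promoter vs gene body; CpG island vs shelf/shore vs open sea),
and for which genes is the tumor-vs-normal expression change concordant
with what the methylation change and the methylation-expression correlation
jointly predict?

The package implements that analysis as a chain of small, testable stages
over two matrices — a probes x samples matrix of 450K-style beta values and
a genes x samples matrix of read counts — plus a manifest-style probe
annotation. Because the motivating cohort sits behind controlled-access
array downloads, the package ships a synthetic-data generator that plants
ground truth (which probes are differential, which genes respond, with what
sign), so every stage can be graded against a known answer.

## The procedure, stage by stage

**Probe filtering.** Probes on sex chromosomes, probes overlapping SNPs or
mapping to multiple genomic locations, and (when a detection p-value matrix
is supplied) probes failing detection (p > 0.01 in any sample) are removed.
Missing beta values are rejected at load time rather than imputed, matching
the upstream convention of dropping probes with missing intensity.

**Differential methylation.** Group comparison is performed on M-values
(`M = log2(beta/(1-beta))`, clipped at `1e-6`), which are far better
behaved near the boundaries of the beta scale, while the *effect size* is
thresholded on the beta scale as delta-beta (mean tumor beta minus mean
normal beta). A probe is a DMP when |delta-beta| > 0.2 and the
Benjamini-Hochberg adjusted p-value is at most 0.005. Two per-probe tests
are provided:

* `dmp_test()` — a self-contained Welch t-test, desk-verifiable and kept as
  the reference implementation of the contract;
* `dmp_test_moderated()` — limma's moderated t (the default in
  `call_dmps()`), i.e. the empirical-Bayes variance squeezing that array
  pipelines such as ChAMP use.

The moderated test is the default because with a 32-vs-5 design the
per-probe variance estimate from five normals is the binding constraint:
on the package's own synthetic cohort the plain Welch test recovers only
~0.85-0.92 of planted DMPs at the 0.005 FDR ceiling, while variance
moderation recovers essentially all of them without inflating the null
(zero calls on a null cohort, tested). The FDR ceiling itself is read as
`adj_p <= 0.005` — an FDR ceiling, not a floor.

**Differential expression.** Genes need at least 5 reads in at least half
of the samples (ceiling for odd sample counts — the stricter reading).
Normalization is median-of-ratios: per sample, the median over
all-nonzero genes of the count divided by the gene's geometric mean,
rescaled to geometric mean one. The test is a two-group negative-binomial
Wald test: per gene, a method-of-moments dispersion pooled across groups
(variance `mu + alpha*mu^2`, floored at `1e-8`) and a Wald statistic on
the difference of log group means with delta-method standard error
`sqrt((1/mu_t + alpha)/n_t + (1/mu_n + alpha)/n_n)`. p-values use a t
reference with `n - 2` degrees of freedom: with 37 samples the normal
reference is measurably anti-conservative (type-I error ~0.055-0.068 at
nominal 0.05 in null simulations; the t reference brings it to
~0.048-0.063, inside the calibration band the test suite enforces). The
test is deliberately simple — no shrinkage of fold changes, no outlier
refitting — because the package's contribution is the integration, and the
caller's operating characteristics are themselves under test. A DEG has
adjusted p < 0.05 and fold change > 2 or < 0.5, where the fold change is
the ratio of mean normalized counts (pseudocount 0.5 per group mean, so a
gene silent in both groups has FC = 1). Fold change on raw counts is
available by flag.

**Correlation (the eQTM-style core).** For every (DMP, annotated gene)
pair whose gene survived the expression filter, the Spearman correlation
between the probe's beta values and the gene's normalized counts is
computed across the *tumor* samples only — coupling is a within-tumor
statement, and the validation arm of the motivating study also correlates
within tumors. (An all-samples mode exists for the ambiguous reading.)
rho is the Pearson correlation of mid-ranks; the p-value uses the
t-approximation with n-2 degrees of freedom, standard at cohort sizes in
the tens; exact permutation p-values are not attempted at n = 32. Pairs
pass at unadjusted p < 0.05, matching the published screen (a BH option
exists but is off by default for fidelity). A probe annotated to the same
gene under several positional labels contributes one pair, classified by
the most promoter-proximal label (priority TSS200 > TSS1500 > 5'UTR >
1stExon > Body > 3'UTR); the six labels collapse to promoter =
{TSS1500, TSS200, 5'UTR, 1stExon} and body = {Body, 3'UTR}, and the six
CpG contexts collapse to island / shelf_shore / open_sea.

**Stratification and concordance.** `ratio_test()` contrasts the
body:promoter ratio between negatively and positively correlated pairs
with a 1-df chi-square (no continuity correction) on the 2x2 sign x region
table. `overlap_with_degs()` inner-joins correlated pairs with the DMP and
DEG tables; `classify_quadrant()` labels each surviving pair: the expected
expression direction is *down* for (hyper, negative) and (hypo, positive),
*up* for (hypo, negative) and (hyper, positive), and a pair is concordant
iff the observed DEG direction matches. Exactly four of the eight label
combinations are concordant, and the classification is invariant under the
simultaneous flip hyper<->hypo, up<->down.

**Enrichment.** A local over-representation test replaces any web-service
query: per gene set, the hypergeometric upper tail of the overlap between
the query and the set, both intersected with a declared universe, BH
adjusted across sets, significant at adjusted p < 0.05. The universe is
the expression-filtered gene set — the genes the analysis could in
principle have returned — not the whole genome.

**Validation statistics.** The targeted-panel arm uses a two-sided
Mann-Whitney U test (exact when `n_x * n_y <= 400` and tie-free, otherwise
the tie-corrected normal approximation), Fisher's exact test for
proportions, relative expression by `2^-(CT_target - CT_reference)`
against a single reference gene, and per-CpG Spearman correlations over a
samples-indexed panel (percent methylation rescaled to [0, 1] on load).

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 32 tumors vs 5
normals; 5% of probes planted as DMPs with 85% hypermethylated and a
beta-scale effect of 0.35; 11% of DMPs coupled to their gene with 70%
negative sign; ~30% of genes differentially expressed at 4-fold (the
published cohort had 3758 of 12778 filtered genes, ~29%); negative-binomial
counts with dispersion 0.2 and log-normal per-sample depth factors
(sd 0.25) recoverable by median-of-ratios. The problem size defaults to
2000 probes x 2000 genes — large enough for stable rate estimates and
binomial calibration bands, small enough that the whole pipeline runs in
seconds.

Mechanics worth knowing:

* Null probes draw beta from a per-probe Beta distribution (precision 100,
  bimodal baseline means) identical in both groups; planted DMPs *add*
  the effect to tumor values on the beta scale, so the planted delta-beta
  is directly the configured effect. Values are kept strictly inside
  [0.002, 0.998] — intensity-ratio betas never reach 0 or 1, and boundary
  values would otherwise become extreme M-value outliers. Planted
  baselines leave noise headroom (shifted tumor means within
  [0.10, 0.90]); residual clipping is counted per probe in the truth table
  and stays well under 1% of planted values.
* Coupling is imposed in tumor samples only: the coupled gene's tumor
  log-mean is shifted by `coupling_sign * coupling_strength * z`, where z
  is that tumor's standardized beta at the coupled probe. So
  `coupling_strength` is the standard deviation (natural-log scale) of the
  expression modulation — 0 disables coupling, and the default 0.8 gives
  within-tumor correlations strong enough to be screened at n = 32.
* Planted DEG status is drawn independently of coupling; the coupling
  modulation is mean-centered, so it does not itself create group-level
  differential expression.
* Randomness is split into three documented streams seeded from the single
  config seed (annotation: seed; methylation: seed + 1; expression:
  seed + 2), so enlarging the probe set does not reshuffle the gene draws.

The generator deliberately omits detection p-values, batch effects,
cell-type composition, per-gene dispersions, probe cross-hybridization
biology (flags are planted at random) and any spatial structure along the
genome. Passing recovery tests therefore demonstrates that the pipeline's
logic and calibration are right under the stated noise model — not that
the thresholds are optimal for real cohorts with those additional
artifacts.

## Numerical choices and degenerate inputs

* Percentages print at one decimal with ties rounded away from zero
  (`round_half_up()`), matching how such tables are conventionally
  printed; base `round()` would round half-even.
* BH adjustment is the classic step-up (`bh_adjust()`), oracle-tested
  against both a brute-force double loop and `p.adjust`.
* A probe with zero variance in both groups and equal means returns p = 1
  by convention (p = 0 when means differ with zero variance); a gene with
  all-zero counts returns p = 1; Spearman on a constant vector is an
  error, and such pairs are skipped and counted in the `skipped`
  attribute rather than silently dropped.
* `estimate_size_factors()` takes the median on the ratio scale; DESeq2
  takes it on the log scale. The two coincide except for even-count
  medians, where they differ by the arithmetic-vs-geometric mean of the
  two central values (the test suite pins agreement on an odd-count
  instance).
* Ties in beta or counts use mid-ranks throughout.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
default 2000 x 2000 cohort (32 + 5 samples) for recovery, a matching null
cohort (nothing planted) for calibration, and an 83-tumor panel of 7 CpGs
for the validation arm. The oracle-equivalence tests use 200+ random small
instances per primitive. These sizes are the package's chosen desk-scale
operating point; all of them are parameters, not constants.

## Known limitations

* The DMP and DEG callers are intentionally standard (moderated t / plain
  NB Wald); they are the scaffolding around the integration, not
  re-implementations of any specific published pipeline's internals.
* The correlation screen uses unadjusted p < 0.05 by construction; its
  false-positive rate is the screen's alpha, which the null-calibration
  tests verify, and downstream conclusions should treat single pairs
  accordingly.
* Gene symbols are the join key between annotation, counts and gene sets
  (matched case-insensitively); no identifier mapping is attempted.
* Multi-gene probes contribute one pair per annotated gene, and one count
  per (gene, region) pair in region tallies — a counting convention, since
  manifests do not dictate one.
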