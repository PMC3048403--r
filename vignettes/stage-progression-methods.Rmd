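---
title: "Stagewise expression analysis of three-stage progression models"
author: "tristage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stagewise expression analysis of three-stage progression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tristage)
```

# The analysis problem

Cell-culture models of neoplastic progression are often sampled at three
stages — an early/benign stage (E), an intermediate/transitional stage (I)
and a late/malignant stage (L) — with a few biological replicates per stage
hybridized to expression microarrays. The scientific questions `tristage`
addresses are:

1. Which probe sets change between the early and late stages?
2. *When* does each change happen — early (complete by the intermediate
   stage), progressively (stepwise across both transitions), or late
   (only after the intermediate stage)?
3. Which functional gene categories are over-represented among the
   changing genes?
4. Do the changes recur in archived data from another species or
   platform?
5. Do bench validation assays (qPCR, western densitometry, F-actin
   fluorescence) agree quantitatively?

The package implements each step as a tested function and couples them to
a synthetic-data generator with known ground truth, so the whole pipeline
can be validated end to end without any external download.

# Model and procedure

## Normalization

Arrays are made comparable by **trimmed-mean scaling**: each array is
multiplied by a scalar so that its trimmed mean (discarding the
`floor(trim * n)` smallest and largest intensities, `trim = 0.02` per tail
by default) equals a target of 500 fluorescence units. Because a positive
rescaling preserves order statistics, the scaled trimmed mean hits the
target to floating-point precision (the tests require 1e-9 relative).
This scaling presumes that the bulk of the transcriptome is unchanged
between arrays; it is accurate when a few percent of probes are
differentially expressed (the regime of a typical progression study) and
degrades if most probes carry planted effects, which is why validation
simulations embed effect probes in a large null background.

## Stage contrasts and the DE filter

For each probe, group means over the replicate arrays of each stage give
three pairwise comparisons — I vs E, L vs E and L vs I — each summarized
by a **signed fold change** (ratio if \(\ge 1\), negative reciprocal
otherwise, so −19.3 means 19.3-fold lower) and a two-sided two-sample
t-test on the linear intensity scale. The pooled-variance (homoscedastic)
test is the default, mirroring the spreadsheet-style analysis such
studies typically use; a Welch variant is available
(`contrastStats(..., variant = "welch")`). Probes with zero within-group
variance get the deterministic convention p = 1 for equal means and p = 0
otherwise. The fold change is computed on normalized linear values, not
logs.

A probe is called differentially expressed when

* its maximum intensity across all arrays exceeds 500 units (strict),
* its |L vs E fold change| is at least 2 (inclusive), and
* its L vs E p-value is at most 0.05 (inclusive).

No multiple-testing correction is applied at this step, matching the
filtering convention of the studies this pipeline reproduces; the
enrichment module reports Benjamini–Hochberg values where they belong.

## Trajectory classification

DE probes are classified by when their change occurs, using fixed
precedence (late, early, progressive, other) at a per-leg significance
level `alpha = 0.05`:

* **late**: `p_IE > alpha` and `p_IL <= alpha` — nothing happened by the
  intermediate stage, then a significant I-to-L change;
* **early**: `|fc_IE - fc_LE| <= 0.4` on the signed fold-change scale,
  with matching signs and `p_IE <= alpha` — the change is already
  complete at the intermediate stage;
* **progressive**: both legs significant with a consistent direction
  across all three ratios;
* **other**: anything else.

Placing **late** first only resolves boundary ties (true plateau probes
fail the early test's `p_IE <= alpha` leg anyway); placing **early**
before **progressive** keeps the early class the small, exclusive set it
is in practice. The 0.4 window is *inclusive* with a 1e-9 numeric
tolerance, because ratios printed to one decimal can sit exactly on the
boundary while `2.6 - 2.2` is not representable exactly in binary. When a
contrast table carries only the two E-referenced columns (as printed
result tables do), the I-to-L leg is unavailable and the L-vs-E
significance and sign stand in for it; with full contrasts the true
I-to-L test is used. With the inclusive window, printed-precision tables
can include borderline genes whose unrounded ratios straddled the
boundary; this is a property of working from rendered values.

## Over-representation

Gene-level DE lists (probes collapsed to unique annotated symbols, a
two-direction gene appearing in both lists with a warning) are tested for
category over-representation with the one-sided **hypergeometric upper
tail**, computed by exact summation: with `N` background genes of which
`K` belong to the set, and `n` DE genes of which `k` belong,
\(P(X \ge k) = \sum_{i=k}^{\min(K,n)} {K \choose i}{N-K \choose n-i} / {N \choose n}\).
The background is the set of genes expressed above the intensity floor.
The significance flag uses the raw p-value at 0.01, the convention of the
published category tables; BH-adjusted values are reported alongside but
do not drive the flag.

## Cross-species concordance

Each mouse gene is looked up (case-insensitive symbol match) in an
archived reference platform's per-gene table and assigned a **percentile
rank**: its 1-based position when the platform is sorted by increasing
p-value (mean rank for ties), divided by the platform size, times 100. A
gene is significant when its rank is at or below `rankThreshold`
(default 10%); genes absent from a platform print as `"x"` and remain in
the denominator `n` but can never be concordant. The overlap summary is
the **cumulative binomial upper tail**
\(\sum_{i=k}^{n} {n \choose i} p_0^i (1-p_0)^{n-i}\)
with per-gene null probability `p_null = rankThreshold/100` by default.
Both the threshold and `p_null` are explicit arguments because archived
comparisons rarely state them; they should be reported with any result.
Direction checking (`checkDirection = TRUE`) additionally requires the
platform fold change to share the mouse direction; it is off by default
so that printed comparison tables — which count opposite-direction
significant genes — are reproduced as laid out.

## Validation-assay statistics

* **qPCR**: per-sample \(\Delta Ct = Ct_{target} - Ct_{reference}\);
  \(\Delta\Delta Ct\) is the difference of group means and the relative
  fold \(2^{-\Delta\Delta Ct}\). The t-test is applied to the
  \(\Delta Ct\) values (standard Livak practice), not to folds.
* **Densitometry**: band intensity over loading-control intensity,
  expressed as percent of the control group's mean ratio, so the control
  group averages exactly 100.
* **F-actin per cell**: \(\bar z = \bar x / \bar y\) (fluorescence over
  cell count) with the quotient propagation-of-error formula
  \(\sigma_z = \bar z\sqrt{(\sigma_x/\bar x)^2 + (\sigma_y/\bar y)^2}\).
  \(\sigma\) denotes the sample (n−1) standard deviation throughout.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; `simulateExpression()`
draws intensities as *baseline × stage effect × multiplicative log-normal
noise*:

* baseline per probe: \(2^{N(7,\,1.2^2)}\) (median ≈ 128 units, so a
  realistic fraction of probes sits below the 500-unit expression floor);
* stage effects by planted class: **early** carries the full fold effect
  (default 4) at I and L; **progressive** half the log2 effect at I
  (i.e. 2-fold) and full at L; **late** the effect at L only; **null**
  none. Directions are up or down with probability 0.5;
* noise: log-normal with coefficient of variation `cv` (default 0.1;
  validation runs use 0.05 where a stronger signal regime is the point),
  unit mean, independent across the 9 arrays;
* default class proportions (early 0.002, progressive 0.015, late 0.026,
  null 0.957) mirror the composition observed in a genome-scale
  progression study, where roughly 4% of ~45,000 probe sets change and
  those split about 59/33/4 percent among late, progressive and early
  patterns. Class counts are deterministic given the proportions; all
  draws are reproducible from the mandatory seed.

Companion generators plant ground truth for the downstream modules:
`simulateGeneSets()` builds gene sets with one set enriched for DE genes
(sampling weight `enrichmentFactor`), `simulatePlatform()` builds a
reference platform in which a chosen fraction of queried genes receives
low-tail p-values and matching fold directions, and `simulateQpcr()`
emits Ct tables whose \(\Delta\Delta Ct\) fold equals the planted fold in
expectation.

What the generator deliberately does **not** emulate: probe-level
summarization artifacts, spatial or batch effects, correlated noise
between replicates, probe-specific variance, and annotation errors.
Passing the recovery tests therefore demonstrates the pipeline's
statistical machinery under clean study-like conditions, not robustness
to every artifact of real array data.

# Numerical choices and degenerate inputs

* Zero-variance groups in a t-test: p is defined as 1 (equal means) or 0
  (unequal), so constant synthetic probes behave deterministically.
* All-zero (or non-positive trimmed-mean) arrays are rejected as
  degenerate rather than silently scaled.
* Signed fold changes require positive means — guaranteed after
  normalization of positive intensities.
* The early-window and rank-threshold comparisons are inclusive with a
  1e-9 tolerance, so printed-precision inputs behave as rendered.
* Tail probabilities are exact finite summations of `dhyper`/`dbinom`
  point masses; tests verify agreement with brute-force enumeration over
  all parameter combinations up to size 12.

# Problem sizes used in validation

The shipped validation runs use: a genome-scale pipeline run of 45,102
probe sets × 9 arrays at CV 5% (classifier recovery, trajectory
fractions); 10,000 null probes at CV 10% (empirical type-I error of the
L-vs-E test, expected 0.05 ± 0.01); 2,000-gene backgrounds with 20 gene
sets × 100 seeds (planted-set enrichment); and 100-seed replicates of the
single-probe and qPCR recovery checks. These sizes give stable
Monte-Carlo estimates while keeping a full validation run to well under a
minute of compute.

# Known limitations

* The pipeline starts from probe-set summary intensities; CEL-level
  summarization is out of scope.
* No ortholog mapping beyond case-insensitive symbol matching in the
  cross-species module.
* The trajectory rules are three-point pattern tests, not a time-course
  model; with only three stages and three replicates the late class
  inherits a ~5% misclassification floor from the type-I error of its
  "no early change" leg.
* Trimmed-mean scaling assumes most genes unchanged; designs where a
  large fraction of the transcriptome shifts need a different
  normalization.

# A compact worked example

```{r example}
cfg <- simulationConfig(nProbes = 4000, cv = 0.05, seed = 42)
sim <- simulateExpression(cfg)
norm <- scaleTrimmedMean(sim$expr)
de <- deFilter(contrastStats(norm))
de
summarizeTrajectory(classifyTrajectory(de))
```
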