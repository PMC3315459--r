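---
title: "Methods: reciprocal-cross imprinting calls and their false-discovery behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-cross imprinting calls and their false-discovery behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recimprint)
```

## The statistical model

At a heterozygous SNP in an F1 hybrid, reads carrying the C57Bl/6J (B)
and CAST/EiJ (C) alleles are counted separately. Under the idealized
model every read is an independent Bernoulli draw, so with no allelic
bias the B count at depth $n$ is $\mathrm{Binomial}(n, 1/2)$, and the
Pearson goodness-of-fit statistic

$$\chi^2 = \frac{(b - n/2)^2}{n/2} + \frac{(c - n/2)^2}{n/2}
         = \frac{(b - c)^2}{n}, \qquad \mathrm{df} = 1$$

measures allele-specific expression (ASE). `ase_chisq()` implements this
without a continuity correction: counts of 30 vs 70 must give
$\chi^2 = 16$, $p = 6.3\times 10^{-5}$ (with the Yates correction they
would give $\approx 9.6\times 10^{-5}$, which is not the convention this
machinery is built on). At small depths the uncorrected statistic is
anti-conservative relative to the exact binomial test; the test suite
documents the size of that gap rather than hiding it, because the point
of the package is to evaluate this exact test, not to improve it.

A unit (SNP, or gene after summing counts over its SNPs) is **called
imprinted** from one sample per cross direction when

1. depth $\ge$ 10 reads in both samples (the unit is "powered"),
2. $p < \alpha$ in both samples (strict inequality; $\alpha = 0.05$ for
   SNP-level replication, $\alpha = 10^{-4}$ for gene-level discovery),
3. the maternal read fraction is on the same side of 0.5 in both
   (maternal allele = B under BxC, C under CxB).

Condition 3 is what separates imprinting from a strain effect: a
cis-regulatory variant biases toward the same *strain* in both crosses
and can never satisfy it, exactly, regardless of depth. The **imprinting
score** is $\pm(-\log_{10} p_\mathrm{used})$ with $p_\mathrm{used}$ the
*less* significant of the two per-cross p-values; we fix maternal =
positive (the sign is pure convention and carries no evidence).

Exact 50:50 ties get direction "none": they can never support a call but
still count as powered in sensitivity denominators. Zero-depth units are
underpowered by definition.

## Why raw p-values cannot be trusted, and the two diagnostics

Real allelic counts violate the binomial model in three distinguishable
ways, which the synthetic generator parameterizes separately:

* **per-SNP systematic offsets** $e_k$ (sequence-dependent alignment and
  library artifacts), shared across all samples. Being cross-symmetric
  they cannot mimic imprinting, but they make two SNPs in the same exon
  disagree;
* **biological/sample variance** $b_{g,s}$ per sample-by-gene, plus
  **overdispersion** $\rho$ (beta-binomial). These *do* produce spurious
  reciprocal patterns between any two samples;
* **strain effects** $s_g$, which are real biology but not imprinting.

Two diagnostics target these:

**Within-exon concordance** (`enumerate_snp_pairs()`,
`discordance_curve()`, `simulate_null_discordance()`). True ASE is a
property of the transcript, so two SNPs in one coding exon must agree in
direction. Pairs closer than 40 bp are excluded (a read can span both,
violating independent sampling; strict "> 40"). Overlapping coding exons
are resolved to the longest (ties to the lower start) so no SNP is
sampled twice through isoforms. The discordance expected from counting
noise alone is reconstructed by simulation: in each pair the *more*
significant SNP is replaced by the partner's allelic ratio scaled to its
own depth (partner 30/20 at total 100 gives expected 60/40), perturbed by
a $\chi^2(1)$ draw through the Pearson quadratic
$(x - e_B)^2(1/e_B + 1/e_C) = \chi^2$ — for expected 60/40 and
$\chi^2 = 1$ the roots are 64.9/55.1, i.e. simulated counts 65 or 55 —
with the root chosen uniformly at random, rounded to integer counts and
clamped to $[0, n]$. Replacing the more significant member keeps the
pair's thresholding p-value (always the less significant one) comparable
with the observed curve; the alternate mode (replace the less
significant) gives still lower expected discordance and is available via
an argument. Rounding before re-testing is the default because the
procedure should be runnable on integer counts; an exact-real mode exists
behind `round_counts = FALSE`. When the partner is monoallelic the
expectation is nudged 0.5 reads inside the boundary so the quadratic is
defined.

**Mock comparisons** (`fdr_curve()` and friends). Two samples of the
*same* cross treated as if reciprocal cannot contain parent-of-origin
signal, so their significant-unit count estimates the false-positive
count at any threshold; dividing by the reciprocal arm's count gives an
empirical FDR. Samples are first depth-normalized — chrX and chrM SNPs
dropped (hemizygosity and uniparental inheritance confound allelic
sampling there), then every sample thinned *without replacement*
(multivariate hypergeometric over its allelic counts, mimicking removal
of aligned reads) to the smallest sample total — and both arms are
always computed from the same normalized table, which the API enforces
by taking a single count table. Pooling across multiple mock (and
reciprocal) pairs is by summing significant counts; set-union pooling is
available behind `pooling = "union"` since the choice is not forced by
anything in the design. Mock pairs prefer same-sex samples when
available (mixed-sex mocks give equivalent counts; the default scheme
builder handles both).

## The synthetic generator

`simulate_reciprocal_dataset()` draws, for SNP $k$ of gene $g$ in sample
$s$ whose mother is strain $m$:

$$\mathrm{logit}\,\theta_B = s_g + e_k + b_{g,s} + I_g\,\beta_g\,
u(m, \mathrm{direction}, \mathrm{sex}), \qquad
b \sim \mathrm{BetaBin}(n, \theta_B, \rho)$$

with $u = +1$ when the expressed parental allele is B in that cross,
$-1$ when it is C, and 0 when the gene is sex-specific and the sample's
sex does not match. Defaults: four samples (both sexes of both crosses,
mirroring a 2×2 reciprocal design), depths log-normal with median 50 and
$\sigma_{\log} = 1$, truncated at 1 — chosen to straddle the 10-read
powering rule; SNP spacings uniform on 10–200 bp so both admissible
(> 40 bp) and excluded pairs occur; $\sigma_\mathrm{strain} = 0.5$,
$\sigma_\mathrm{snp} = 0.3$, $\sigma_\mathrm{bio} = 0.25$ (workflow) /
0.2 (constructor), $\rho = 0.01$, 10% of genes imprinted with
$\beta \sim N(2, 0.5)$ truncated at 0.5 (a logit effect of 2 puts the
expressed allele at $\approx 88\%$, typical of robust imprinting).
The magnitudes of $\sigma_\mathrm{snp}$, $\sigma_\mathrm{bio}$ and
$\rho$ in any real library are unknown — the experimental literature
demonstrates their consequences, not their values — so these defaults
are explicitly synthetic: chosen once to place the generator in the
qualitative regime where both diagnostics have something to detect, and
labelled as such.

The decomposition itself (offsets shared across samples vs
sample-specific deviations) is a modelling choice: shared offsets
inflate same-exon discordance but cancel between crosses, while
$b_{g,s}$ and $\rho$ drive mock-comparison false positives. What passing
tests on this generator shows is that the estimators behave correctly
when the data violate the binomial model *in these ways*; real libraries
can also contain alignment bias correlated with the SNP alleles
themselves, reference bias, and cell-composition effects that no term
here emulates, so calibration on synthetic data is necessary but not
sufficient evidence for calibration on a real experiment.

`truth_eval()` closes the loop: confusion counts of any call table
against the generative truth, which is how the test suite verifies that
the mock-FDR estimator tracks the true FDR across thresholds
$10^{-2}$–$10^{-5}$ under overdispersion.

## Numerical and procedural choices

* Coordinates are 0-based half-open internally (BED native); VCF POS is
  converted by −1 on ingest. SNP-in-exon containment is strict half-open
  (a SNP at position 20 is outside $[0, 20)$).
* A SNP inside two overlapping genes contributes to both aggregates and
  is flagged `multi_gene`; nothing in the calling rule depends on the
  flag. Reads spanning two SNPs of one gene are double-counted by
  aggregation — unavoidable when only count tables exist, and accepted
  because the procedure being evaluated aggregates identically.
* Thresholds are strict (`p < alpha`, separation `> 40`); a p-value
  exactly at a threshold never passes.
* Gene direction under SNP-replication calling comes from the most
  significant imprinted SNP, ties broken by lowest genomic coordinate;
  candidate ranking breaks remaining ties by gene id so the order is
  total.
* Sex-specific classification refuses to claim specificity when the
  non-significant sex is underpowered.
* The pyrosequencing rule is applied per replicate pairing by default
  ("both replicates must meet the criteria" read strictly); an averaged
  mode exists behind an argument. The 2-SD threshold corresponds to a
  nominal normal $p \approx 0.0228$ one-sided; the caller reports
  distances in SD units (`z_units`) and makes no p-value claim.
* `extrapolate_total()` is the generic estimator
  $(\mathrm{confirmed} + r \cdot \mathrm{untested})/\mathrm{sensitivity}$.
  Published figures produced by this style of arithmetic are not always
  reconstructible from their printed operands, and this package makes no
  attempt to force agreement; the function is exact for its stated
  inputs.

## Problem sizes

The test suite and acceptance checks run at sizes chosen for sharp
statistical conclusions at interactive cost: $10^5$ SNPs for null
calibration of the caller (rate $\approx 2(\alpha/2)^2 = 1.25\times
10^{-3}$ at $\alpha = 0.05$, so $\sim 125$ expected events), 400–600
genes for FDR-tracking and recovery checks, $2\times 10^4$ SNP pairs for
the null-discordance bound, and 100 iterations for downsampling and
discordance-null bands. The analysis workflow uses a 600-gene, 4-sample
dataset throughout.

## Known limitations

* The chi-square machinery is evaluated, not replaced: no beta-binomial
  test, no GLM, no analytic FDR model — the empirical mock estimator is
  the contribution under study.
* Only count tables are consumed; there is no read-level processing, so
  alignment bias can be diagnosed (via discordance) but not corrected.
* BED12 is the only gene-model format; GTF/GFF ingest is out of scope.
* The pyro caller consumes instrument-quantified percent-bias values;
  trace parsing and assay chemistry are out of scope.
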