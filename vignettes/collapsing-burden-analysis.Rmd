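---
title: "Rare-variant collapsing burden analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing burden analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmhburden)
```

## The statistical problem

Most protein-altering variants are individually too rare to test for
disease association. Collapsing analysis buys power by taking the gene
as the unit: all *qualifying* variants in a gene are aggregated and each
sample is dichotomized as carrier (at least one qualifying alternate
allele) or non-carrier — a dominant coding of the gene's rare-variant
burden. In a multi-cohort case-control study the carrier/non-carrier by
case/control counts form one 2×2 table per recruitment stratum, and the
Cochran–Mantel–Haenszel (CMH) machinery combines them under a
common-odds-ratio alternative. The CMH test is a natural choice here
because it remains well behaved at the low — even zero — cell counts that
rare-carrier tables routinely produce.

This vignette records the models this package implements, the parameter
defaults and why they are what they are, the numerical choices, and what
the synthetic-cohort tests can and cannot certify about real data.

## Qualifying variants

A variant qualifies when it is rare — minor allele frequency (MAF)
strictly below `maf_max = 0.01` in *every* ancestry group — and
predicted damaging: protein-truncating (stop-gained, start-lost,
frameshift, canonical splice-site), or missense with CADD scaled score
strictly above `cadd_min = 10` (the top 10 % most deleterious
substitutions on CADD's phred-like scale). Both bounds are strict as
written: MAF exactly 1 % and CADD exactly 10 do not qualify.

Two points were genuinely open and decided here:

* **Which allele frequencies.** MAF is computed from the post-QC
  genotypes of the combined case+control dataset, grouped by the country
  strata (the study's ancestry groups are its recruitment countries);
  external per-population frequency columns (`ext_af_*`), when supplied,
  are folded and subjected to the same bound as an additional
  constraint. A variant whose frequency is undefined in every group
  (no called genotypes) conservatively fails.
* **Unknown carrier status.** A sample whose calls are missing at every
  qualifying variant of a gene is *unknown* for that gene and excluded
  from that gene's tables, rather than counted as a non-carrier, which
  would deflate carrier frequencies.

## Quality control

Thresholds live in `qc_thresholds()` and are never hard-coded at call
sites. The variant-level cascade runs in a fixed, logged order:

1. calls with depth < 10 reads are set missing;
2. heterozygous calls with allelic balance outside the open interval
   (0.20, 0.80) are set missing (boundaries fail); hets lacking allelic
   depths are skipped and counted;
3. variant call rate must exceed 0.95, evaluated *after* the masking;
4. Hardy–Weinberg exact test within every country stratum on all samples
   of the stratum, excluding at P < 10⁻⁴;
5. case-control differential genotype missingness (Fisher exact),
   excluding at P < 10⁻³;
6. decomposed multi-allelic records fail together: if any sibling of a
   site fails, all siblings fail.

Design notes. HWE is computed per country on all samples (cases
included), matching the stratify-then-filter description of the
workflow. The allelic-balance rule is applied at the call level (mask,
then re-evaluate call rate); whether the original procedure masked calls
or dropped whole sites is ambiguous, so `ab_action = "drop"` is
available as a switch, with masking the default. Depth is likewise
enforced per supporting call rather than per site. Fisher's exact test
is used for differential missingness (no test is named in the source
description); exact tests are preferred throughout for rare-count
robustness. The test is necessarily phenotype-aware; every other variant
filter is blind to phenotype, and the suite verifies this by permuting
phenotype labels and comparing outcomes filter by filter.

Sample-level QC fails samples with ≤ 80 % of target bases at 20×,
completion rate < 95 %, outlying heterozygote or singleton counts
(both tails; unusually few singletons suggests cross-contamination,
unusually many suggests poor DNA), ancestry-PCA outliers, and
duplicates/first-degree relatives. "Outlying" is operationalized as
|value − stratum median| > 4 MAD, a conventional robust-z cutoff, since
the source description says only "extreme"; strata under 10 samples skip
the robust screens with a warning. Relatedness uses the KING-robust
kinship estimator with the standard thresholds (0.354 duplicates,
0.0884 first-degree); one of each flagged pair is kept, preferring
cases, then the higher call rate. The KING estimator needs on the order
of a few thousand informative SNPs before its noise floor clears the
0.0884 threshold — the reason the simulator's common-variant block
defaults to 2,000 sites.

Ancestry PCs come from LD-pruned (greedy scan, pairwise r² < 0.1) common
variants: dosages are centred at 2p̂ and scaled by √(2p̂(1−p̂)), missing
values mean-imputed, and the top 5 axes extracted by SVD with each
axis's sign fixed by its largest-magnitude loading, making scores
deterministic.

VQSLOD-based site filtering is out of scope (it requires the upstream
recalibration model); a numeric pass-through threshold is provided for
data that carry the annotation.

## Association statistics

The CMH statistic is computed on raw counts with no continuity
correction — with the published single-stratum validation table
(24/1,735/3,864/464,016) this choice reproduces the printed P = 0.013
(χ² = 6.19), which a Yates-corrected statistic would not. The
Mantel–Haenszel common OR takes a Robins–Breslow–Greenland CI (no CI
method is named in the source; RBG is the standard choice and is also
what `stats::mantelhaen.test` produces, which the test suite exploits as
an independent implementation, agreeing to 10⁻¹⁰). Single-table display
ORs use Woolf intervals with the Haldane–Anscombe +0.5 correction when
any cell is zero; the CMH statistic itself never uses corrected cells.
All P values are two-sided, and multiple testing is the fixed
exome-wide threshold 2.5 × 10⁻⁶, not FDR.

One identity worth recording: for a single stratum the CMH statistic
equals the Pearson chi-square times (n−1)/n — the hypergeometric
variance carries the n−1 — so "CMH equals Pearson" holds exactly only in
that rescaled sense; at cohort sizes the difference is far below
printing precision.

The covariate-adjusted burden model is a logistic regression of case
status on the carrier indicator plus the top 5 ancestry PCs and the
exome-wide variant count (all standardized), maximum likelihood by
default. Separation — common when carriers are few — is detected from
non-convergence, boundary fitted probabilities, or an exploding carrier
coefficient, and triggers a Firth-penalized refit (hat-diagonal-modified
score, Newton iteration, implemented in the package), recorded in the
result.

Secondary analyses rebuild the tables under post-hoc restrictions:
female-only and male-only (both cases and controls filtered by sex),
acute-subtype cases versus *all* controls (controls are never
subtype-restricted), and the combination. `carrier_pc_projection()`
provides the standard confounding diagnostic: carriers of a flagged gene
projected on PC1/PC2 with report-only location tests.

## The synthetic-cohort generator

`sim_config()` defaults describe the study design the analysis assumes,
scaled to desk size: four country cohorts with the empirical
case:control ratio, 62 % female cases (the reported series was 38 %
male), ~31 % of cases with the acute subtype, one spiked risk gene at
1 % control carrier frequency with carrier OR 2.14, rare-variant allele
frequencies from Beta(0.2, 200) truncated at 5 % (a rare-skewed
stand-in; the real site-frequency spectrum of the cohorts is not public,
so the law is exposed in the config), consequence classes with CADD
scores that include non-qualifying decoys (synonymous sites, low-CADD
missense), Poisson(60) per-call depth, Binomial(depth, ½) heterozygous
allelic balance with optional extra Beta noise, 0.5 % base missingness
with optional per-stratum batch offsets, and a 2,000-site common-variant
block carrying a configurable per-stratum allele-frequency shift (PCA
recovers it when positive) and 10 % noisy duplicate sites to give the LD
pruner something to remove.

Risk-gene carriers are drawn per stratum with control probability
`q` and case probability from the exact odds transform
`p = OR·q / (1 − q + OR·q)` — exact rather than the rare-disease
relative-risk approximation, because at desk scale the difference is
measurable. Each carrier receives one heterozygous qualifying variant,
chosen uniformly among the gene's qualifying variants: uniform rather
than frequency-weighted so that no single spiked variant accumulates
enough carriers to drift above the 1 % MAF bound and silently drop out
of the qualifying set. Everything else segregates independently of
phenotype under Hardy–Weinberg. One global seed drives a single
generator stream; identical seed and config give byte-identical files.

What passing tests on these data do *not* show: the generator has no
haplotype structure (LD is induced only by site duplication), no
sequence context or mutation-rate model, no genotype-likelihood
uncertainty, and its artifact models are parametric idealizations. Tests
certify the statistical machinery — filters remove what they are defined
to remove, estimators recover what was planted, size and coverage are
nominal — not robustness to every failure mode of real exomes.

## Statistical power

`analytic_power()` is the classic normal-approximation power of the
two-proportion comparison (pooled-variance critical value, unpooled
alternative variance, case frequency from the exact odds transform,
strata pooled by size); `simulated_power()` draws per-stratum counts
binomially and runs the actual CMH test, vectorized, with a binomial
Monte-Carlo SE. The suite additionally ties the simulation to an exact
enumeration of the rejection probability — the rigorous anchor — and
characterizes the normal approximation against the simulation: accurate
to about one percentage point typically, up to about three points deep
in the tail (exome-wide alpha, expected carrier counts below ~30), which
is the approximation's genuine accuracy limit, not a defect of either
path.

Both a **carrier-based** parameterization (one Bernoulli trial per
person at the carrier frequency) and an **allele-based** one (two trials
per person, i.e. a comparison of allele counts) are implemented, and
every report names which one it used, because the two differ hugely: at
the discovery sample size with cumulative burden 1 % and OR 2.0 at
exome-wide alpha, the allele-based calculation gives ≈ 87 % power and
the carrier-based ≈ 27 %. The reported design power figures (88 %;
86.8 % at 0.5 %/OR 2.5; > 90 % at 2 %/OR 1.7) were produced by an
unstated method; tabulating both parameterizations
(`power_grid()`, and the acceptance script) shows the allele-based
regime tracks those figures closely while the carrier-based one does
not. The package reports the tabulation and does not force agreement.

## Numerical choices and degenerate inputs

* Exact HWE P values are computed from the conditional distribution of
  the heterozygote count given the allele count in log-factorial space;
  ties with the observed probability are included using a 1 + 10⁻¹⁰
  relative tolerance (the convention exact-test implementations use).
* 2×2/stratified arithmetic is done in doubles throughout — biobank-size
  tables overflow 32-bit integer products.
* Degenerate gene tables (zero variance in every stratum) yield `NA`
  statistics, flagged, never dropped; strata missing cases or controls
  are dropped with a log entry; an all-zero carrier predictor in the
  adjusted model returns a flagged non-estimate.
* Zero-variance variants are excluded before LD pruning; constant
  variants after imputation are dropped before PCA.
* Half-missing genotypes (`./1`) are treated as missing — their handling
  is undocumented in the source procedure, and missing is the
  conservative reading.

## Problem sizes used by the suite

Chosen so the full suite and the acceptance script each run in a couple
of minutes on one core while keeping every statistical check
well-powered: exhaustive exact-test enumeration to 30 diploids (HWE) and
table total 40 (Fisher); 1,000 random multi-stratum tables against the
independent CMH implementation; 250 discovery-scale (4,667/5,473,
4 strata) parameter-recovery replicates; 10,000-replicate null
calibration; 10,000–50,000-replicate power cells; and end-to-end
pipeline runs of a few hundred samples by a few thousand variants.

## Known limitations

Alignment and variant calling are upstream and out of scope; no
genotype likelihoods, phasing, or reference-genome awareness; no
kernel/weighted burden alternatives (SKAT-type), recessive models,
heterogeneity statistics, or meta-regression; sex-check and
contamination-from-reads QC are not implemented. Printed results that
require per-stratum counts available only in controlled-access or
supplementary sources (the discovery and combined meta-analysis P
values, the hospital-panel meta OR, the de-novo validation OR, the
adjusted discovery P) are deliberately not asserted anywhere; the
property suites above stand in for them.
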