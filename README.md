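# cmhburden

Gene-based collapsing analysis of rare, protein-altering variants in
stratified case-control exome studies — the design used to search for
genes in which "qualifying" variants (rare, predicted-deleterious) are
carried more often by affected individuals than by controls, as in exome
studies of primary angle-closure glaucoma (PACG) and other late-onset
diseases. It is written for statistical geneticists who want the whole
chain — QC, qualifying-variant selection, dominant collapsing, stratified
association, power — as tested, reusable R functions, exercisable end to
end on synthetic cohorts without any controlled-access data.

## The model

Each gene is the unit of analysis. A sample is a **carrier** if it has at
least one alternate allele at any qualifying variant of the gene, where a
variant qualifies when

* minor allele frequency < 1 % in **every** ancestry group, **and**
* it is protein-truncating (stop-gained, start-lost, frameshift,
  canonical splice-site), **or** a missense with CADD scaled score > 10.

Carriers vs non-carriers against case/control status gives one 2×2 table
per recruitment stratum *k*, with cells *a_k* (case carriers), *b_k*,
*c_k*, *d_k*. The strata are combined with the Cochran–Mantel–Haenszel
test (no continuity correction),

```
X² = ( Σ_k (a_k − E_k) )² / Σ_k V_k ,
E_k = (a_k+b_k)(a_k+c_k)/n_k ,
V_k = (a_k+b_k)(c_k+d_k)(a_k+c_k)(b_k+d_k) / (n_k² (n_k − 1)) ,
```

with a two-sided P from χ²₁ and exome-wide significance at
P < 2.5 × 10⁻⁶ (Bonferroni for ≈20,000 genes). The effect size is the
Mantel–Haenszel common odds ratio Σ(a_k d_k/n_k) / Σ(b_k c_k/n_k) with a
Robins–Breslow–Greenland confidence interval; 2×2 tables containing a
zero cell get the Haldane–Anscombe correction (+0.5 to every cell).
Upstream, the package implements the full exome QC cascade (per-call
depth ≥ 10×, heterozygous allelic balance strictly inside 20–80 %,
variant call rate > 95 %, per-stratum Hardy–Weinberg exact test at
P ≥ 10⁻⁴, case-control differential missingness at P ≥ 10⁻³, the
decomposed multi-allelic sibling rule, sample coverage/completion/
heterozygosity/singleton screens, ancestry PCA on LD-pruned common
variants, KING-robust relatedness), a covariate-adjusted logistic burden
model with a Firth fallback, secondary sex/subtype-restricted analyses,
and analytic plus simulation-based power for the collapsing design.

## Worked example

A published single-stratum validation table — 24 carriers among 1,759
cases and 3,864 carriers among 467,880 controls — directly:

```r
library(cmhburden)
st <- data.frame(stratum = "UKB", a = 24L, b = 1735L,
                 c = 3864L, d = 464016L)
mh_common_or(st)$or        # 1.661  (carriers at ~1.66-fold odds in cases)
mh_common_or(st)$ci        # 1.109 2.488
cmh_test(st)$chisq         # 6.191
cmh_test(st)$p             # 0.0128 (two-sided)
carrier_frequency(st)$case_pct      # 1.4  (% of cases carrying)
carrier_frequency(st)$control_pct   # 0.83
```

And end to end on a synthetic two-cohort study with one spiked risk gene
(control carrier frequency 3 %, carrier odds ratio 3):

```r
cfg <- pipeline_config(
  simulate = sim_config(
    seed = 1,
    strata_spec = data.frame(label = c("SG", "HK"),
                             n_cases = c(350L, 350L),
                             n_controls = c(350L, 350L)),
    n_genes = 30L, n_common = 600L,
    risk_genes = list(risk_gene_spec("GENE0001",
                                     control_carrier_freq = 0.03,
                                     odds_ratio = 3))),
  alpha_exome = 0.05 / 30, out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
head(res$results, 3)
#>       gene or_mh ci_low ci_high chisq  p_cmh exome_wide_significant
#> 1 GENE0001 3.217  1.448    7.14  9.14 0.0025                  FALSE
#> 2 GENE0025 0.455  0.169    1.22  2.55 0.1103                  FALSE
#> 3 GENE0013 2.337  0.727    7.51  2.14 0.1433                  FALSE
```

The spiked gene ranks first with an estimated odds ratio of 3.2
(true value 3 inside the interval); the run directory holds the QC
reports, the per-gene summary statistics, the secondary (sex- and
acute-subtype-restricted) scans, the coverage profile and a JSON-lines
stage log, all reproducible bit-for-bit from the same seed.

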