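# xpqtl

Cross-platform proteomics concordance and pQTL analysis, with
protein-altering-variant (PAV) adjustment.

## The problem

Aptamer-based (RFU-scale) and antibody-based (NPX-scale) affinity
proteomics frequently disagree about the same protein in the same
plasma sample. One established mechanism is the epitope artifact: a
protein-altering variant (missense, start-loss, stop-gain, stop-loss)
changes the epitope a reagent binds, so the two platforms can report
effects of *opposite sign* for the same variant — an apparent cis-pQTL
that reflects binding, not abundance. Because PAV allele frequencies
differ across ancestry groups, these artifacts also make
platform agreement ancestry-dependent.

`xpqtl` is for analysts with multi-platform proteogenomic cohort data
(or anyone studying the phenomenon) who want a tested, reproducible
pipeline for:

* per-protein inter-platform Pearson correlation, with ancestry
  stratification and a Fisher-Z / Cochran's-Q heterogeneity test
  (`Q = Σ (n_g−3)(z_g − z̄)²`, `χ²` with K−1 df) under Bonferroni
  control;
* cis/trans pQTL association scans on rank-inverse-normal, residualized
  measures, with deterministic stepwise-conditional fine-mapping into
  Wakefield-ABF 95% credible sets
  (`ABF = √(se²/(se²+W)) · exp(z²W / 2(se²+W))`, prior `W = 0.04`),
  LD-based (`r² > 0.1`) credible-set deduplication;
* cross-platform signal classification (concordant / discordant /
  platform-only) at shared sentinel variants, PAV flags,
  allele-frequency chi-square ancestry-differentiation scoring
  (75th-percentile rule), and merged 1 Mb trans-pleiotropy regions;
* PAV adjustment (residualization on allele dosage) with quantified
  pre/post correlation, heterogeneity, phenotype-association and pQTL
  changes, including the `newly_associated` no-overlap-no-LD rule;
* protein–phenotype models (linear for age/BMI, logistic for sex/T2D)
  and negative-control limits of detection
  (`median + 3·SD`, raw scale only);
* a synthetic cohort generator (Balding–Nichols ancestry-differentiated
  frequencies, planted epitope effects, covariates, phenotypes,
  negative controls) with closed-form correlation oracles, so the whole
  pipeline is testable without any external data.

## Worked example: a discordant, ancestry-differentiated PAV

Scenario "D" plants a missense variant with epitope effects
`delta_A = -1`, `delta_B = +0.5` and an African-enriched frequency
contrast (0.45 vs ≈0.04), alongside a concordant cis-regulatory
variant, in a cohort of 2,000 across four ancestry groups:

```r
library(xpqtl)
cfg    <- scenario_config("D", n = 2000)
cohort <- simulate_cohort(cfg, seed = 42)
res    <- run_pipeline(cohort, pipeline_config(scan_trans = FALSE), "out")

res$concordance[, c("r_overall", "r_AFR", "r_AMR", "r_EAS", "r_EUR", "Q", "p_het")]
#>   r_overall     r_AFR     r_AMR     r_EAS     r_EUR        Q        p_het
#> 1 0.4226099 0.3455103 0.5505972 0.5488908 0.4681421 22.22402 5.859141e-05
```

The two platforms correlate at 0.42 overall, but agreement is markedly
lower in the group where the PAV is common (AFR, r = 0.35), and
Cochran's Q rejects homogeneity (p = 5.9e-5). Fine-mapping finds both
cis signals on each platform; the PAV signal has opposite directions:

```r
res$pairs[, c("category", "compared_variant", "beta_A", "beta_B")]
#>                 category compared_variant     beta_A    beta_B
#> 1 overlapping_discordant             pav1 -0.6240352 0.4190897
#> 2 overlapping_concordant             cis1  0.3866678 0.3949981
```

The pipeline auto-detects the discordant PAV and adjusts both
platforms' measures for its allele dosage:

```r
res$adjustment$report[, c("pav_id", "r_pre", "r_post", "delta")]
#>   pav_id     r_pre   r_post     delta
#> 1   pav1 0.4226099 0.552769 0.1301591
```

Adjustment raises the cross-platform correlation from 0.42 to 0.55, in
line with the closed-form expectation for these generator settings
(`expected_cross_platform_r(cfg)` = 0.416 pre, 0.526 post — the single
seed-42 cohort sits a little above both).

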