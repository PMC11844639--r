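---
title: "Cross-platform proteomics concordance, pQTL mapping, and PAV adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform proteomics concordance, pQTL mapping, and PAV adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpqtl)
```

## The measurement problem

Two affinity-proteomics technologies dominate large cohort studies:
aptamer-based assays reporting relative fluorescence units (RFU) and
antibody-based assays reporting normalized protein expression (NPX).
Both infer abundance from the binding of a reagent to an epitope on the
target protein. When the same plasma samples are measured on both
platforms, per-protein correlations are often modest, and — more
troubling — the degree of agreement can differ between ancestry groups.

A key mechanism is the protein-altering variant (PAV): a missense,
start-loss, stop-gain or stop-loss variant that changes the protein's
epitope without necessarily changing its true abundance. A PAV can
raise the apparent abundance on one platform and lower it on the other,
because each reagent binds a different epitope. Since PAV allele
frequencies often differ across ancestry groups, epitope artifacts
translate into *ancestry-dependent* measurement error. This package
implements the full analysis chain for detecting and correcting this
phenomenon, and a synthetic cohort generator that reproduces its
statistical structure so every stage is testable without any external
data.

## The generative model behind the analysis

For one protein target, sample $i$ with covariates $c_i$ (age, sex,
site, plate), cis-regulatory dosage $G^{cis}_i$, and PAV dosage
$G^{pav}_i$:

$$U_i = \beta_{cis} G^{cis}_i + \gamma' c_i + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2_{sh})$$
$$M^A_i = U_i + \delta_A G^{pav}_i + e^A_i,\qquad
  M^B_i = U_i + \delta_B G^{pav}_i + e^B_i$$

$U$ is the shared (true-abundance plus shared-covariate) component;
$\delta_A, \delta_B$ are platform-specific epitope effects, possibly of
opposite sign; $e^A, e^B$ are platform noise with variances
$\sigma^2_{eA}, \sigma^2_{eB}$. Ancestry enters through the genotypes:
group $k$ draws dosages $\mathrm{Bin}(2, q_k)$ under Hardy–Weinberg
equilibrium, with subpopulation frequencies $q_k$ either fixed or drawn
from the Balding–Nichols model
$q_k \sim \mathrm{Beta}\!\left(p_0 \tfrac{1-F_{ST}}{F_{ST}},
(1-p_0)\tfrac{1-F_{ST}}{F_{ST}}\right)$, which has mean $p_0$ and
variance $F_{ST}\, p_0 (1-p_0)$.

Writing $\sigma^2_U = \mathrm{Var}(U)$ and $v_G = \mathrm{Var}(G^{pav})$,
the expected cross-platform Pearson correlation is

$$r_{pre} = \frac{\sigma^2_U + \delta_A \delta_B v_G}
  {\sqrt{(\sigma^2_U + \delta_A^2 v_G + \sigma^2_{eA})
         (\sigma^2_U + \delta_B^2 v_G + \sigma^2_{eB})}},\qquad
  r_{post} = \frac{\sigma^2_U}
  {\sqrt{(\sigma^2_U + \sigma^2_{eA})(\sigma^2_U + \sigma^2_{eB})}}$$

where $r_{post}$ is the correlation of the residuals after regressing
both platforms' measures on the PAV dosage. Under group structure with
weights $w_k$ the pooled dosage variance is
$v_G = 2\bar q(1-\bar q) + 2\,\mathrm{Var}_w(q_k)$ — the between-group
term matters when frequencies are strongly differentiated.
`expected_cross_platform_r()` evaluates these formulas from a
simulation configuration and serves as the independent oracle for the
adjustment machinery: with discordant effects ($\delta_A \delta_B < 0$)
the numerator of $r_{pre}$ is penalized while both denominators grow,
so PAV adjustment must *increase* the correlation, by a predictable
amount.

## Stage by stage

**Transformation.** Each probe is standardized by the rank-based
inverse normal transformation
$\Phi^{-1}\!\left(\frac{r_i - c}{m - 2c + 1}\right)$ with offset
$c = 0.5$ (configurable via `int_offset`), average ranks for ties, and
missing values preserved. Correlations and epidemiological models use
this transformed layer; QTL mapping additionally residualizes it on the
covariate design (age, sex, site, plate, optional genotype and protein
principal components).

**Concordance and heterogeneity.** For each UniProt target measured on
both platforms, the probe pair with the highest all-samples correlation
is selected (`best_probe_pair()`, deterministic lexicographic
tie-break), per-ancestry correlations are computed over complete pairs
(samples labeled `unassigned` are excluded from stratification, not
from the overall estimate), and cross-ancestry heterogeneity is tested
by Cochran's Q on Fisher-Z transformed correlations with weights
$w_g = n_g - 3$, referred to $\chi^2_{K-1}$. Groups with $n_g < 4$
carry non-positive weight and are excluded with a warning. The
significance level is Bonferroni-corrected for the number of probe
pairs actually tested.

**pQTL mapping and credible sets.** Association scans are per-variant
simple regressions on residualized measures ($\beta =
\mathrm{cov}(g,y)/\mathrm{var}(g)$, $t$-based p on $n-2$ df; missing
dosages are mean-imputed for scans only, never for allele-frequency
counting). Cis is the closed 1 Mb window around the transcription start
site; everything else is trans. Significance requires a credible-set
member with $p < 5\times10^{-8}$ (cis) or $p < 10^{-11}$ (trans).
Fine-mapping is a deterministic stepwise-conditional procedure: forward
rounds pick the top variant and residualize on its dosage (up to
`max_signals = 5` rounds); a refinement pass then recomputes each
signal's statistics conditional on the other signals' leads and forms
the 95% credible set from Wakefield approximate Bayes factors
$\mathrm{ABF} = \sqrt{\tfrac{se^2}{se^2+W}}
\exp\!\left(\tfrac{z^2 W}{2(se^2+W)}\right)$ with prior variance
$W = 0.04$, normalized to posterior inclusion probabilities. The
refinement step is what keeps each credible set specific to its own
signal: when two independent signals have comparable marginal strength,
a purely marginal first round would put both causal variants into one
set, and the downstream LD filter would then collapse two real signals
into one. ABFs are computed on the log scale — at desk-scale effect
sizes $z^2/2$ routinely exceeds the overflow point of `exp()`.
Credible sets for the same probe whose members are in LD
($r^2 > 0.1$) are deduplicated, keeping the set with the more
significant lead (greedy, visiting sets by ascending lead p).

**Cross-platform classification.** Credible-set pairs for the same
protein sharing at least one member are *overlapping*; direction is
compared only when one platform's sentinel (lead) is contained in the
other platform's set, using that variant's per-platform betas (each
set records its members' per-round statistics for exactly this
purpose). Same sign: concordant; opposite: discordant; overlap without
a shared sentinel is left uncompared. Ancestry differentiation of a
variant is a Pearson chi-square on the groups-by-{alt, ref} allele
count table ($df = K-1$), flagged when the statistic exceeds the
empirical 75th percentile (linear-interpolation quantile, strict
comparison) of all tested variants. Pleiotropic trans regions are
1 Mb windows (± 500 kb, configurable) around significant trans
sentinels, merged transitively across platforms when they overlap;
a region with ≥ 5 proteins on both platforms is shared-pleiotropic,
≥ 5 on one and ≤ 1 on the other is platform-specific, anything else
is not pleiotropic.

**PAV adjustment.** For discordant pairs whose compared sentinel (or
any shared member) is protein-altering for the encoded gene, both
platforms' measures are residualized on the PAV dosage (additive
0/1/2 term), and the pipeline reports pre/post overall and per-ancestry
correlations and heterogeneity. Post-adjustment cis remapping includes
the PAV as a genuine covariate (both the phenotype and each candidate
dosage are residualized on it — the Frisch–Waugh–Lovell route to the
multiple-regression coefficient, with degrees of freedom reduced
accordingly). Post sets are matched to pre sets by shared members or
cross-set LD ($r^2 > 0.1$); matched sets are strengthened/attenuated by
lead p, unmatched post sets are newly-associated.

**Epidemiology and LOD.** Phenotype models treat the phenotype as
outcome and the protein as predictor: linear for age and BMI, logistic
for sex and prevalent T2D, with plate and site as covariates (plus age
and sex for BMI/T2D). This direction is the only one coherent across
the binary outcomes, and the wording of the source conventions is
ambiguous, so it is fixed here and documented. The limit of detection
is `median(negative controls) + 3 * SD(controls)` per probe, computed
on the raw scale only — the pipeline refuses transformed input — with
the SD pooled across all negative controls of a probe (per-plate SDs
are a config variant left out of scope). The fraction of samples above
LOD uses a strict inequality.

## What the generator does and does not emulate

`simulate_cohort()` reproduces: K ancestry groups with
Balding–Nichols-differentiated frequencies (default $F_{ST} = 0.12$,
typical of continental-scale differentiation) plus an optional
`unassigned` fraction; HWE genotypes; shared abundance with cis,
covariate and optional trans-hub effects; platform-specific epitope
effects of configurable sign; per-platform noise; phenotypes linked to
the first protein's shared component; and per-probe negative controls.
The scenario catalogue covers the qualitative regimes: concordant cis
signal (A), single-platform epitope effect (B), a shared trans hub
driving six proteins (C), the discordant ancestry-differentiated PAV
(D), and a null protein (E).

Scenario D's defaults are the study conditions for the recovery
properties: $\delta_A = -1$, $\delta_B = +0.5$ (an epitope artifact as
large as the biological signal on the aptamer side, half as large and
opposite on the antibody side) and PAV frequencies
(0.45, 0.05, 0.02, 0.05) across the four groups — an African-enriched
contrast of the kind seen for Duffy-null-like variants. A milder
contrast (e.g. frequencies 0.14/0.53/0.60/0.32) still produces
discordant classification and the correlation gain, but the per-group
correlation differences become too small for the cross-ancestry
heterogeneity test to have high power at $n = 2000$; the analytic
noncentrality of Cochran's Q under the AFR-enriched defaults is ≈ 17,
giving power ≈ 0.95 at the synthetic study's own Bonferroni level.

The generator deliberately does **not** emulate: realistic LD maps
(variants are simulated independently, so dedup and newly-associated
logic is exercised through constructed fixtures rather than reference
haplotypes), admixed individuals (each sample belongs to one group),
plate batch effects, assay-specific saturation or hook effects, or
non-Gaussian heavy-tailed noise. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real plasma proteomics.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and all windows are closed intervals.
* Multi-allelic VCF records are rejected unless splitting is requested.
* Scans refuse $n < 10$; monomorphic variants are skipped with a flag;
  zero-residual fits are flagged degenerate rather than reported with
  $se = 0$.
* The allele-frequency chi-square with pooled EAF 0 or 1 is defined as
  0 with $p = 1$ and flagged.
* Logistic separation is flagged and no estimate is returned.
* `residualize()` errors on rank-deficient designs, naming the
  collinear columns, and is idempotent to $10^{-10}$.
* Monomorphic PAV dosages make `pav_adjust()` the identity, with a
  warning.
* Ties in probe-pair selection break lexicographically; dedup visits
  sets by ascending lead p. All pipeline stages are deterministic given
  the inputs, so reruns are byte-identical.

## Problem sizes used by the test suite

The suite and the acceptance script run at desk scale, chosen so the
whole battery completes in well under an hour on one CPU: cohorts of
2,000 (four groups of 500) for the scenario-D recovery properties (100
replicates) and the trans-hub region test; 1,000 replicates for the
null calibrations of both heterogeneity tests; oracle-equivalence
checks at $n \le 50$ (machine precision against `lm()` and
`chisq.test()`); and a 20,000-sample single cohort for validating the
closed-form correlation oracle to ±0.02.

## Known limitations

* The stepwise-conditional fine-mapper is a deterministic stand-in for
  sum-of-single-effects-style Bayesian fine-mapping; its credible sets
  are per-signal conditional sets, not joint posteriors, and `W` is a
  fixed prior variance rather than estimated.
* Covariate adjustment in QTL scans is by pre-residualization of the
  phenotype (plus true covariate inclusion for the PAV term in
  post-adjustment mapping); with covariates correlated to genotype this
  differs slightly from joint estimation.
* EAF-based differentiation uses all genotyped samples with an
  ancestry label; relatedness filtering is assumed upstream.
* One PAV is adjusted per protein; joint multi-PAV or haplotype-aware
  adjustment is out of scope.
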