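---
title: "Linking FDG avidity to the glucose/lipid metabolic balance in HCC: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking FDG avidity to the glucose/lipid metabolic balance in HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmetab)
```

## The model

Hepatocellular carcinoma spans a wide range of FDG avidity, and high
uptake is prognostically adverse. `petmetab` operationalizes the
hypothesis that avidity reflects a one-dimensional *metabolic shift*:
tumors that reprogram toward glycolysis (and HIF-1 signaling) and away
from fatty-acid oxidation (and PPAR signaling) accumulate more FDG and
behave more aggressively.

The imaging phenotype is the tumor-to-liver ratio
$\mathrm{TLR} = \mathrm{SUV}_{max}(\text{tumor}) /
\mathrm{SUV}_{mean}(\text{liver})$, a within-patient normalization that
removes most scanner and dosing variation. Expression enters as paired
tumor/normal $\log_2$ fold changes, so each patient is their own
control. For a gene set $S$ and z-scored expression $z_{gi}$, the
gene-set signature score is the unweighted mean
$\mathrm{GESS}_i(S) = |S|^{-1} \sum_{g \in S} z_{gi}$, and the
metabolic balance score is
$\mathrm{MBS}_i = \mathrm{GESS}_i(\text{glucose}) -
\mathrm{GESS}_i(\text{lipid})$. MBS is a contrast of two program
means: it is positive when glycolytic genes sit above their cohort
average while lipid-handling genes sit below it, and it is exactly
antisymmetric under swapping the two programs.

The analysis makes the usual assumptions of this design: Pearson
correlation (approximate bivariate linearity on the chosen scales;
$\log_2$ TLR is the default uptake scale because uptake ratios are
naturally multiplicative), unadjusted per-gene testing at
$\alpha = 0.05$ in the screen (the screen is a *candidate filter*, not
an inference procedure; a BH option exists), and proportional hazards
for everything survival-related.

## Workflow and tunable parameters

**Discovery** (`run_discovery()`): TMM factors → CPM → paired
$\log_2$ FC (pseudocount 0.5) → per-gene z-scores → Pearson screen of
the candidate list against $\log_2$ TLR → sign-split programs → GESS /
MBS → optional hypergeometric ORA. **Validation**
(`run_validation()`): per-endpoint univariable Cox screen
($p < 0.1$) → intersection into the biomarker set → greedy
collinearity exclusion ($|r| \ge 0.8$) → multivariable Cox →
prognostic index → median split → KM/log-rank → per-gene t-tests → MBS
zero-cutoff stratification → mutation chi-square.

Parameters that matter, with defaults and rationale:

| parameter | default | meaning / why |
|---|---|---|
| `screen_alpha` | 0.05 | raw two-sided p threshold of the Pearson screen |
| `cox_alpha` | 0.1 | univariable Wald-p threshold feeding the multivariable model |
| `collinearity_r` | 0.8 | absolute Pearson cutoff of the greedy exclusion pass |
| `mbs_cutoff` | 0 | balanced-metabolism point; MBS ≥ 0 is the glycolysis-dominant risk group |
| `pseudocount` | 0.5 | added to CPM before ratios; keeps FC finite and pair-swap antisymmetric |
| TMM trims | 0.30 (M), 0.05 (A) | the canonical published trim fractions |
| `ties` | "efron" | Cox tie correction; "breslow" available (and the one under which subject-duplication invariance is exact) |
| `tlr_scale` | "log2" | uptake variable for the screen; "raw" available |

All thresholds are surfaced through the YAML config; none is
recomputed from data.

## Numerical choices, ties and degenerate input

- **z-scores** use the sample SD ($n-1$), matching the defaults of the
  statistical software family this analysis style comes from.
  Zero-variance genes are dropped and logged, never silently NaN'd.
- **Ties at any cutoff go to "high"**: TLR at the median is the high
  phenotype, MBS at zero is high risk, PI at the median is high risk.
  One rule everywhere, chosen to mirror the explicit
  at-or-above-median TLR convention; the even-$n$ median is the
  midpoint of the two central order statistics.
- **TMM reference tie** (two samples equidistant from the mean upper
  quartile): lexicographically first sample id, for determinism.
- **Perfect correlations** report $p = 0$ (the limit of the
  t-transform) rather than a clamped minimum; downstream use is
  threshold-based only.
- **Wald CIs** use the conventional 1.96 multiplier, so
  $\mathrm{CI} = \exp(\beta \pm 1.96\,\mathrm{SE})$ holds exactly in
  the output tables.
- **Genes missing from a cohort** are logged and skipped in GESS and in
  the screen (a curated list never fully intersects a real matrix);
  empty intersections are hard errors.

## Design decisions where the design was open

- **Screen input**: fold changes (the quantity the discovery design
  constructs) rather than tumor-only expression; `screen_input =
  "tumor"` switches. In validation cohorts without paired normals,
  z-scores are taken directly on $\log_2(x+1)$ tumor expression — the
  fold-change step is discovery-only.
- **Collinearity rule**: "excluded due to collinearity" is
  operationalized as a greedy pass in ascending univariable-p order,
  excluding a gene when $|r| \ge 0.8$ against any kept gene. This is
  deterministic, keeps the stronger member of a correlated pair, and
  removes exactly one member of a tight pair.
- **Cox engine**: fitting is delegated to `survival::coxph` (the
  field-standard partial-likelihood implementation); the package's
  contribution is the workflow around it, and the test suite checks
  the fitted coefficients against an independent brute-force
  maximization of a hand-written partial likelihood.
- **TMM is implemented in-package** (the screen's input depends on
  it), and cross-checked against `edgeR::calcNormFactors` to 1e-8 in
  the tests — two independent routes to the same definition.
- **PI median split** is computed within the validation cohort; no
  external threshold is assumed or imported.
- **Mutation calls**: any variant listed in the MAF counts as mutant;
  no variant-classification filter is applied (and none is exposed),
  since the stated analysis provides no such rule.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws, per patient, a single latent axis
$a_i \sim N(0,1)$ that drives everything: glucose-program fold changes
$+\beta_{glu} a_i$, lipid-program fold changes $-\beta_{lip} a_i$
(background 0), all with $N(0, \sigma_{fc})$ gene-level noise;
negative-binomial counts around the implied means (dispersion 0.1,
log-normal library-size variation); $\log_2 \mathrm{TLR}_i = \gamma_0 +
\gamma_1 a_i + N(0, \sigma_{tlr})$ with TLR floored at 1 (tumors are
never colder than liver); exponential survival with hazard
$h_0 \exp(0.4 \cdot \mathrm{MBS}^{true}_i)$ and uniform censoring; and
TP53/CTNNB1 mutations with logistic odds of opposite sign in $a_i$.

The defaults state the emulated study's world: 60 patients, a
404-gene curated candidate list containing a 9-gene glucose and a
21-gene lipid program, liver SUVmean $\sim N(2.2, 0.3)$, and
$\gamma_0, \gamma_1$ chosen so the median TLR lands near 1.7–1.9 with
range roughly 1–7. Values the stated world leaves free were fixed once
at field-realistic levels — $\sigma_{fc} = 0.8$ (gene-level FC noise of
the same order as the planted effect), NB dispersion 0.1 (typical
human-tissue bulk RNA-seq), baseline abundance log-normal around 200
counts, a 120-month censoring window over a 0.015/month baseline
hazard (≈50% event rate) — and not revisited.

Deliberately *not* emulated: multiple latent axes (immune, stromal,
proliferative programs that correlate with metabolism in real tumors),
batch effects, isoform/copy-number structure, non-proportional
hazards, and dependence between DFS and OS beyond their shared hazard.
A green recovery test therefore establishes that the pipeline is
correct *under its own assumptions* — not that a real cohort would
show effects of this size, nor that a one-axis model is biologically
sufficient.

## What the tests establish

The suite checks every operation against an independent route: TMM vs
`edgeR`, Pearson p vs a 200,000-draw permutation null, hypergeometric
p vs exhaustive enumeration on small universes, Cox coefficients vs
brute-force 1-D likelihood maximization, KM vs a hand-written
product-limit estimator and `survival::survfit`. Calibration tests
verify the α-level of the screen under a simulated global null, the
≈10% retention of a null univariable Cox screen, and 95% Wald CI
coverage within [93%, 97%] at $n = 300$. Recovery tests verify ≥90%
sign-correct recovery of planted programs at $n = 250$ and recovery of
the planted MBS log-hazard within 2 SE. No empirical claim appears in
this vignette that those tests (or `scripts/acceptance.R`) do not
themselves compute.

## Known limitations

- The external validation targets (hazard ratios in a public cohort)
  depend on the expression scale and data release used; the package
  defaults to $\log_2(x+1)$ per-unit HRs and exposes the transform,
  but exact reproduction of externally printed HRs is out of scope
  offline.
- The screen's raw-p design deliberately trades specificity for
  sensitivity; derived programs contain α-level false positives by
  construction, which the ORA stage (and set curation) is meant to
  absorb.
- Greedy collinearity exclusion is one deterministic reading of
  "excluded due to collinearity"; variance-inflation-based rules would
  keep slightly different sets when correlation is diffuse rather than
  pairwise.
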