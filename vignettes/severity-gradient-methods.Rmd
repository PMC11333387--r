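---
title: "Methods: a treatment-access gradient for low back pain severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a treatment-access gradient for low back pain severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbpburden)
```

## The problem

Years lived with disability (YLDs) are prevalence × disability weight (DW),
where a DW in (0, 1) scores the severity of a health state. For low back
pain, burden estimation frameworks have historically applied one severity
distribution — derived from US survey data — to every country and year. Where
access to effective interventions is worse than in the US, that assumption
understates severity; where it is better, it overstates it. This package
implements a pipeline that makes the average low back pain DW a function of a
country's Health Access and Quality (HAQ) Index, and decomposes the burden
into what current treatment already averts, what better access could avoid,
and what no existing treatment can touch.

## Model and procedure

### Treatment effects

Trial arm summaries (n, mean, SD per arm on a functional-disability scale)
become bias-corrected standardised mean differences (Hedges g):

$$ g = J \frac{\bar x_a - \bar x_b}{s_p},\qquad
   J = 1 - \frac{3}{4(n_a+n_b-2)-1},\qquad
   \mathrm{var}(g) = \frac{n_a+n_b}{n_a n_b} + \frac{g^2}{2(n_a+n_b)} . $$

Negative g means less disability in the intervention arm. Trials with
follow-up outside 3–12 months (inclusive) are dropped, then any
non-reference class with fewer than 10 retained trials is dropped together
with its trials (iterated to a fixed point, since removing trials can push
other classes under the threshold). Excluded classes contribute **zero**
effect downstream — they are treated as untreated exposure, since no pooled
effect exists for them.

Pooling assumes consistency on a connected network: trial effects satisfy
$y_i = d_{a(i)} - d_{b(i)} + u_i + e_i$ with the usual-care reference fixed
at $d_{\text{ref}}=0$, $e_i \sim N(0, v_i)$, and a common between-trial
heterogeneity $u_i \sim N(0, \tau^2)$ shared by all contrasts (the data do
not support contrast-specific heterogeneity). $\tau^2$ is the generalized
DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - (n-p))/c\big)$ with
$c = \mathrm{tr}(W) - \mathrm{tr}\big((X'WX)^{-1}X'W^2X\big)$, and the class
effects are weighted least squares with weights $1/(v_i+\hat\tau^2)$.
Uncertainty is carried as 1000 draws from
$N(\hat\beta, (X'W X)^{-1})$ — a parametric, frequentist stand-in for
posterior sampling that satisfies the same recovery properties and keeps the
pipeline dependency-free.

### Crosswalk and attribution

A calibration set of health states with known DWs and SF-12 scores
identifies the crosswalk $\mathrm{logit}(DW) = a + b\,\mathrm{SF12}$, fitted
by ordinary least squares with multivariate-normal coefficient draws. The
crosswalk is kept linear in logit space with no spline: the calibration
sample (62 states by default) is too small to support more structure, and
linearity makes every downstream regression exact in the synthetic world.

Each respondent's SF-12 score then yields a *cumulative* DW covering all
their conditions. A survey-weighted regression of logit cumulative DW on all
condition indicators (low back pain split into with/without leg pain, plus
every comorbidity) supports the counterfactual "drop the low back pain
terms": with $DW_{full}$ and $DW_{cf}$ the model predictions with and
without those terms, the attributable weight is the multiplicative share

$$ DW_{attr} = DW_{obs}\,\big(1 - DW_{cf}/DW_{full}\big) \in [0, DW_{obs}], $$

the comorbidity-style arithmetic that guarantees attribution never exceeds
the observed total. Because the crosswalk is affine in SF-12, this condition
model is fitted *once* as a weighted regression of SF-12 on the indicators
and mapped through the crosswalk coefficients; its draws multiply the
crosswalk's draws index-by-index, which is exactly equivalent to refitting
per draw and propagates both uncertainty sources coherently.

### Counterfactual scenarios

Reported treatments combine multiplicatively,
$SMD_{overall} = 1 - \prod_i (1 - SMD_i)$ (empty product → 0; harmful
positive SMDs such as bed rest are handled symmetrically), and are removed by

$$ SF12_{notreat} = SF12 + SMD_{overall}\,\sigma_{SF12}, $$

with $\sigma_{SF12}$ the survey-weighted SD of observed SF-12 among all low
back pain respondents (both strata pooled — the method defines a single
scale factor). The full-use-of-optimal-treatment (FUOT) scenario applies the
combined psychological + physical class to the no-treatment score; reported
sub-optimal treatments confer no residual benefit because they were already
stripped. Among leg-pain cases, 42.9% (the complement of the 57.1%
spontaneous disc-prolapse regression fraction) receive the surgery effect
instead. The fraction is applied as a deterministic population weight — in
score space for the scalar `apply_fuot()`, in DW space inside
`summarize_scenarios()` — rather than Bernoulli assignment: the expectation
is identical and no Monte-Carlo noise is added. Per draw d, each scenario's
scores pass through draw d of the crosswalk, and the comorbidity component
$DW_{obs} \cdot DW_{cf}/DW_{full}$ is held fixed across scenarios (the
scenarios move low back pain severity, not the comorbid burden).

### Gradient and burden decomposition

Stratum scenario means combine with a configurable leg-pain fraction into
three anchors. Country–year DWs are **linear in DW space** (not logit space
— the method is defined as interpolation of the average disability weights):

$$ DW(h) = DW_{notreat} + (DW_{obs} - DW_{notreat})\,h / h_{anchor}, $$

with $DW_{notreat}$ at HAQ 0 and the observed anchor at
$h_{anchor} = 83.6$ (the observed-treatment setting). Beyond the anchor the
line is extrapolated — the highest-HAQ countries must be able to fall below
the anchor value — but floored at the FUOT weight: no country can outperform
full optimal treatment. Per draw and country,

* untreated burden: $YLD_{nt} = prev \cdot DW_{notreat}$,
* averted: $YLD_{nt} - YLD_{current}$,
* avoidable with best routine care: $YLD_{current} - prev \cdot \widehat{DW}(\text{highest-HAQ country})$,
* avoidable with FUOT: $YLD_{BRC} - YLD_{FUOT}$,
* unavoidable: $YLD_{FUOT}$,

which telescope to $YLD_{nt}$ identically, so shares of the untreated burden
(the denominator the method implies when it speaks of reducing the
*untreated* burden) sum to 100% per draw at every aggregation level.
Aggregation sums components per draw over regions, super-regions, and
globally, then recomputes shares. Intervals are the 25th/975th ranked values
of 1000 draws, every stage indexing the same draw labels.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_draws` | 1000 | draws | matches the canonical 25th/975th interval ranks |
| `followup_window` | [3, 12] | months | stated eligibility window, inclusive |
| `min_trials_per_class` | 10 | trials | stated class-exclusion rule |
| `surgery_eligible_fraction` | 0.429 | — | complement of 57.1% spontaneous regression |
| `haq_anchor` | 83.6 | HAQ | observed-treatment setting (high-income North America, mid-survey period) |
| `legpain_fraction` | 0.30 | — | leg-pain share among low back pain; unstated in the source material, so configurable and reported in the manifest |
| `gbd_dw` | 0.096 | DW | treatment-invariant reference weight for the percent-change report |

## The synthetic world

The generator *states* a world whose parameters are the published point
values, so recovery tests are interpretable on the published scale:

* true class SMDs = the published pooled point estimates (`lbp_class_smds()`);
* coverage = the published proportions by leg-pain status
  (`lbp_class_coverage()`; "not surveyed" classes get 0, "<0.1%" gets 0.001);
* true crosswalk: intercept 2, slope −0.08 per SF-12 point (fixed by the
  worked example logistic(2 − 0.08·50) = 0.1192);
* observed attributable DWs 0.103 (no leg pain) and 0.169 (leg pain);
* trial world: 200 trials, arm sizes 30–200, between-trial SD 0.1 (a typical
  τ for SMDs in this literature), 70% of trials versus usual care, 85% of
  follow-ups inside the window;
* respondents: 25% with low back pain, 30% of those with leg pain,
  log-normal survey weights with mean 1 (sdlog 0.5), three comorbidities
  (arthritis, depression, diabetes) with DW increments 0.05/0.145/0.03 and
  prevalences 0.20/0.10/0.10 — unstated in the source, chosen once as
  plausible mid-range values; SF-12 measurement noise SD 3 points.

Respondents are generated in the *observed* state: SF-12 equals a healthy
baseline (80) minus constant per-condition decrements plus noise, which
makes logit DW exactly linear in the condition indicators — the attribution
model is the true model, so attribution tests isolate estimation error from
model misspecification. The low back pain decrements are calibrated at
configuration time (root finding over the enumerated comorbidity
distribution with Gaussian quadrature over the noise) so the stratum mean
observed attributable DW equals the 0.103/0.169 targets *exactly* in
expectation. Treatment indicators are independent across classes given
leg-pain status (only marginal coverages are stated); the untreated truth
column adds each respondent's own combined effect back via the removal
equation, so removal recovers it exactly by construction.

`sim_truth()` computes, by exact enumeration over comorbidity × treatment
combinations and a 200-point equal-probability quadrature over the noise,
the analytic population values of every quantity the pipeline estimates —
scenario DWs by stratum, combined SMDs, anchors, country DWs, and global
shares. This is the independent oracle for the end-to-end recovery test.

Two stated targets cannot coexist in this world: with slope −0.08 and the
world's SF-12 spread (σ ≈ 14.8), removing the stated treatment effects from
observed DWs 0.103/0.169 yields no-treatment DWs ≈ 0.122/0.212, not the
published 0.132/0.228 (whose implicit slope·σ product is larger). The
generator keeps the observed severity and the true effects as stated; the
no-treatment truth *follows* from them, and recovery tests target the
analytic truth. A green suite therefore establishes that the pipeline
recovers a coherent world stated from the published values — not that it
reproduces headline numbers that depend on restricted microdata. Features of
real data the generator does not emulate: panel structure and nonresponse,
ICD-coded condition extraction, item-level SF-12 scoring, two-wave SF-12
averaging, correlation between treatment use and severity, and multi-arm
trials.

## Numerical choices

* DWs at the unit-interval boundaries are clamped to [1e-6, 1−1e-6] before
  logit (`clamp_dw()`); the transform is undefined at the bounds.
* $\hat\tau^2$ is floored at 0; a fixed τ (e.g. 0) can be supplied for
  closed-form checks.
* Coefficient draws use a Cholesky factor; a numerically zero covariance
  (saturated two-point crosswalk) degenerates to repeated means.
* Report rounding is half-to-even (DWs 3 decimals, percentages 1 decimal),
  with values snapped to `digits + 8` decimals first so that binary
  representation noise (e.g. `0.006/0.096·100 = 6.25 + 5e-15`) cannot flip
  the rounded digit; percent changes are computed from the *rounded* DW, as
  printed reports imply.
* Degenerate inputs error with typed conditions: constant SF-12 calibration
  column, collinear condition design (offenders named), disconnected
  network (unreachable classes named), duplicate country–years, wrong draw
  counts. Empty coverage strata are flagged as empty, never reported as 0.
* With 1000 draws the interval ranks are exactly 25 and 975; for other draw
  counts the generalisation `ceiling(0.025 n)` / `floor(0.975 n)` is used
  (tests scale draws down for speed).
* The end-to-end recovery test allows 3 SEs over seeds plus 0.25 percentage
  points, fixed a priori, for plug-in bias (estimated σ, fitted
  coefficients) that does not shrink with the number of seeds.

## Design choices where the method was open

* **Averted vs avoidable labelling**: the two published summaries attach
  17.6%/9.1% to different scenario labels; this package defines *averted* as
  current-treatment vs no-treatment and *avoidable (BRC)* as the
  highest-HAQ-country increment, the reading consistent with the
  decomposition closing at 100%.
* **Multi-treatment joint distribution**: only marginals are stated;
  independence given leg-pain status is the minimal completion.
* **Single SF-12 summary score** on a 0–100 scale; component handling is
  not specified by the method.
* **Eq-1 draws**: class SMDs enter per draw (not as point values per
  respondent), so pooled-effect uncertainty propagates into every scenario.
* **Estimation backend**: frequentist WLS with parametric draws rather than
  MCMC; the method's published tool is proprietary-adjacent and its priors
  unpublished, and the recovery properties are backend-agnostic.

## Limitations

* The gradient inherits the HAQ Index's limits as an access proxy; the
  interpolation is linear by definition, not by evidence.
* Coverage, not effectiveness, varies by country; effect sizes are assumed
  portable across scales and settings.
* The published region table evidently passes through additional severity-
  distribution machinery (its anchor-HAQ value is below any leg-pain-weighted
  combination of the published stratum DWs); this package reproduces its
  percent-change arithmetic from printed inputs but not that machinery.
* Attribution shares are model-based; with real (non-synthetic) data the
  logit-linear condition model is an approximation, and its misspecification
  is not captured by the draw-based intervals.
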