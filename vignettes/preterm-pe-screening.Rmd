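---
title: "Competing-risks screening for preterm preeclampsia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing-risks screening for preterm preeclampsia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescreen)
```

## The screening problem

Preeclampsia (PE) is a hypertensive disorder of pregnancy, diagnosed as
new hypertension with proteinuria after 20 weeks' gestation. Its preterm
form — delivery before 37 weeks — carries most of the perinatal burden
and is the form that prophylactic aspirin, started in the first
trimester, can largely prevent. First-trimester combined screening
therefore tries to find, at 11–14 weeks, the women who will go on to
preterm PE, using maternal history plus four biomarkers: mean arterial
pressure (MAP), mean uterine artery pulsatility index (UtAPI), and the
serum markers PAPP-A and PlGF. This package implements the full analysis
pipeline such a screening evaluation needs.

## The competing-risks model

The engine treats the gestational age at delivery with PE as a latent
variable $g$ (weeks). A pregnancy develops preterm PE when $g < 37$,
term PE when $37 \le g < B$ for a boundary $B$, and no PE at all when
$g \ge B$ — delivery happens before PE can occur. This makes "no PE" a
competing outcome rather than a separate class.

**Prior.** $g \sim N(\mu(\text{history}),\ \sigma^2)$. Each binary risk
factor adds a configured shift (weeks) to $\mu$; age, weight and height
enter linearly around reference values. All coefficients live in a
single `risk_model_parameters()` object, serializable to versioned YAML.

**Likelihood.** Given $g$, the vector of log$_{10}$ MoMs is multivariate
Gaussian with covariance $\Sigma$ and broken-stick means
$m_k(g) = a_k + b_k \max(0, \text{knot}_k - g)$: at or beyond the knot a
pregnancy is biochemically indistinguishable from an unaffected one, and
with the default intercepts $a_k = 0$ unaffected pregnancies center on
1 MoM, which is what "multiple of the median" promises. Negative slopes
for PlGF and PAPP-A (lower values imply earlier $g$) and positive slopes
for MAP and UtAPI give the directed monotonicities the markers are known
for. Missing markers are handled by marginalization — the likelihood
uses the covariance sub-matrix of the observed markers — never by
imputation.

**Posterior.** Bayes' rule over a dense grid in $g$; the preterm-PE risk
is the normalized posterior mass below 37 weeks. Prior mass beyond the
no-PE boundary stays in the normalization — that is the competing-risk
structure at work: strong markers can only raise the risk insofar as
they outweigh the prior mass parked on "never develops PE".

## Parameter defaults and their provenance

The published risk engines embed proprietary coefficient sets that the
validation literature does not print. The package is therefore **fully
parameterized**, and the shipped `default_risk_params()` is an explicitly
synthetic stand-in, calibrated once so that the default simulated
population reproduces the headline quantities a South Asian screening
cohort reported: preterm-PE incidence 1.34% and total-PE incidence 3.17%
(solving for the baseline prior mean 53.34 weeks and no-PE boundary
39.79 weeks with $\sigma = 7$), history-alone discrimination around AUC
0.76 (scaling the history effects), and a detection-rate ladder at 10%
FPR that climbs from roughly 45% (history alone) to above 80% (all four
markers) across the standard combination order (choosing marker slopes
0.0055, 0.030, −0.050, −0.058 for MAP, UtAPI, PAPP-A, PlGF, knots at 40
weeks). Marker SDs follow typical unaffected log$_{10}$ MoM spreads
(0.031, 0.133, 0.255, 0.215); correlations are modest (0.20 between the
biochemical pair, ±0.03–0.10 elsewhere). These defaults make every
downstream stage self-consistent and testable; they are not a clinical
risk calculator.

Tunable parameters that matter most, with defaults:

| Parameter | Default | Units / meaning |
|---|---|---|
| `preterm_cutoff` | 37 | weeks; defines preterm PE |
| `no_pe_boundary` | 39.79 | weeks; competing no-PE outcome |
| `prior_sd` | 7 | weeks; prior spread of $g$ |
| risk threshold | 1:100 | high-risk classification (inclusive) |
| `target_fpr` | 0.10 | DR read-off point |
| `aspirin_effect` | 0.6 | assumed preterm-PE risk reduction |
| QC `alpha`, `band` | 0.05, [0.98, 1.02] | re-centering trigger |

## Numerical choices

The posterior is integrated by the trapezoid rule on a grid with step
0.02 weeks. The grid spans 10–95 weeks: the bounds are a numerical
device, not a clinical statement — they cover more than ±5 prior SDs for
realistic profiles, so the grid-normalized risk agrees with untruncated
closed forms to well below $10^{-6}$, and the quadrature error at the
37-week read-off stays below $10^{-6}$ whenever the posterior SD exceeds
about one week. Beyond the largest marker knot the likelihood is
constant in $g$, so the implementation walks the grid only up to that
point and adds the remaining prior mass as a single Gaussian tail term;
this is an exact rearrangement up to quadrature error and makes
cohort-scale risk computation (tens of thousands of women, all marker
subsets) take seconds. Profiles that stack several large negative
history shifts (prior mean below ~45 weeks) push prior mass below the
grid floor; their risks are then grid-normalized by construction, which
is the model's stated behaviour, but closed-form comparisons at
$10^{-6}$ no longer apply to them. The "1:N" display rounds $1/p$ half
away from zero; classification always uses the raw probability, so a
woman at risk 0.0100 is high risk at 1:100 while 0.0099 is not.

## MoM quality control

Validation studies repeatedly find that MoMs computed with coefficients
developed elsewhere are miscentered in a new population. The QC stage
mirrors the conventional procedure exactly, including its quirk: the
*test* is a one-sample t-test of the **mean** of the log$_{10}$ MoMs in
unaffected pregnancies against zero, while the *correction* divides by
the **median** of the MoMs. Both statistics are carried in the
`RecenteringReport` so the discrepancy stays visible (a mean-implied
median of 0.85 can coexist with an empirical median of 0.86). A
statistically significant deviation whose median lies inside
[0.98, 1.02] is deliberately left uncorrected — at cohort sample sizes a
t-test flags medians of 0.99 that no one would treat as clinically
meaningful miscentering. Re-centering forces the unaffected median to
exactly 1 (mid-order-statistic median, so exactly 1 also at even $n$),
is idempotent, and is scale-equivariant.

## The synthetic cohort generator

`simulate_cohort()` realizes the model it is later analysed with:
profiles are drawn from truncated-Gaussian and categorical marginals
(defaults follow a published screening cohort's characteristics table:
age 30.9 ± 4.0 years, weight 63.1 ± 10.9 kg, height 159.5 ± 5.5 cm,
chronic hypertension 1.6%, diabetes 2.8%, SLE/APS 0.3%, assisted
conception 5.2%, parity 60/38/2%), $g$ from the history prior, outcomes
from $g$ against the cutoff and boundary, and log$_{10}$ MoMs from the
marker likelihood at $g$ (no-PE women draw from the zero-mean unaffected
distribution). Population miscentering multiplies the MoMs by
configurable per-marker factors (defaults 0.99/0.99/0.86/0.87 for
MAP/UtAPI/PAPP-A/PlGF); the unshifted values are kept for ground-truth
checks. Screening gestation is uniform on 11+0 to 13+6 weeks. Aspirin
is assigned *after* classification, to 17.4% of screen positives by
default, and prevents each would-be preterm case with probability 0.6,
independent of dose; a prevented case is relabelled term PE with
delivery redrawn between the cutoff and the boundary ("prevented or
delayed"), with relabel-to-no-PE available by configuration. The
generator is bit-reproducible given its mandatory seed.

What the generator does **not** emulate: joint dependence between risk
factors (only marginals are published; a BMI–hypertension correlation
hook would be a natural extension), miscarriage and loss-to-follow-up,
assay batch effects, and any real-world deviation from the Gaussian
log-MoM model. Passing tests on synthetic cohorts therefore demonstrate
the *pipeline's* correctness and calibration under the stated model, not
the clinical performance of any particular coefficient set — the
screen-positive rate of a real cohort, for instance, depends on exactly
the joint structure the generator does not claim to reproduce.

## Aspirin counterfactual and weighted evaluation

Once screening triggers prophylaxis, observed case counts understate the
risk the test detected. With an assumed effect $e$, each observed
preterm-PE case in a treated woman stands for $1/(1-e)$ would-be cases
(2.5 at $e = 0.6$). Two conventions are implemented because the
published arithmetic is internally inconsistent: `additive_paper` adds
$2.5 \times$ the observed treated cases *on top of* the observed total
(reproducing printed totals like 25 observed + 15 prevented = 40
adjusted), while `counterfactual` reads the same formula literally and
adds $1.5 \times$. The default reproduces the printed arithmetic. At
$e = 0$ nothing can have been prevented, so both conventions collapse to
the identity — the one point where the additive reading is overridden.

For ROC analysis the prevented cases have no observed risk scores. The
package gives each observed treated case the extra weight implied by the
convention instead of inventing pseudo-records, so prevented cases
inherit the empirical score distribution of the observed treated cases
and the weighted ROC, DR-at-FPR and AUC stay well defined. The DR at a
fixed FPR uses the conservative empirical convention — the most
permissive cutoff whose FPR does not exceed the target, no interpolation
— which is why reported DRs are multiples of one over the (weighted)
case count. AUC confidence intervals use a seeded stratified bootstrap
(cases and controls resampled separately, each woman keeping her weight,
percentile bounds, 2,000 replicates by default); the analytic DeLong
interval is not defined for these weights, but the unweighted AUC is
cross-checked against an independent implementation in the tests.

The AUC sample-size helper uses the Hanley–McNeil variance
approximation with an explicit control:case ratio, in two modes
(standard error target, or power against a null AUC). Published
sample-size statements of the form "26 cases for AUC 0.9, SE 5%, α 5%,
power 80%" do not pin down the formula — no standard reading reproduces
that count, and at a 3% case rate 26 cases implies far fewer screened
women than such studies quote — so the helper returns its assumptions
alongside the count and the package asserts no equality with any
published figure.

## Problem sizes in the test suite

The suite exercises the engine against a 10×-finer brute-force
integrator on 100 randomized instances and against the conjugate closed
form in a linear-likelihood regime; recovery of injected MoM shifts and
the decile calibration of risks use cohorts of 20,000; the end-to-end
ordering property (AUC and DR ladder improving as markers are added)
uses ten seeded cohorts of 20,000. These sizes give binomial/median
sampling error comfortably inside the asserted tolerances while keeping
the default test run to a few minutes.

## Known limitations

* The default coefficients are synthetic stand-ins; nothing here
  reproduces any proprietary software's risk outputs, version
  differences, or term-PE risks (all out of scope).
* The marker likelihood assumes Gaussian log MoMs with a covariance
  shared between affected and unaffected pregnancies.
* The expected-median models shipped for raw-measurement conversion are
  likewise synthetic defaults; fitting median regressions from raw
  population data is out of scope.
* Extreme multi-factor histories are truncation-limited at the grid
  floor, as described under numerical choices.
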