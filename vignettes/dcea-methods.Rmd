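---
title: "Model and methods: distributional cost-effectiveness of liquid-biopsy-first testing in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdcea)
```

## The question

Patients with advanced non-small cell lung cancer (aNSCLC) should receive
broad genomic profiling before first-line therapy, but up to 30% have
insufficient tissue for NGS. For them, two diagnostic strategies compete:
repeat the tissue biopsy (TB-only), or sequence circulating tumor DNA first
and fall back to tissue only when the liquid biopsy (LB) is negative
(LB-first). LB is less sensitive (and cannot measure PD-L1 expression) but
returns results roughly three weeks sooner, and driver-mutation prevalence —
hence the benefit of finding one — differs sharply across race and ethnicity
subgroups (EGFR alterations: ~52% of Asian patients versus ~13% of NH-White
patients). `lbdcea` estimates not only the average health and cost
consequences of LB-first but their *distribution* across NH-White, NH-Black,
Asian and Hispanic subgroups: a distributional cost-effectiveness analysis
(DCEA).

## Model structure

**Decision tree.** For each subgroup the model enumerates every diagnostic
outcome. The eight driver mutations are mutually exclusive; the test panel is
evaluated sequentially in the published marker order, so each positive call
(true positive on the patient's own mutation with the marker-specific
sensitivity, false positive on any other with one minus its specificity) is
conditional on all previous markers being negative. A patient whose panel is
fully negative — probability \((1-Se_m)\prod_{m'\neq m} Sp_{m'}\) for a true
mutation \(m\) — proceeds to the next stage: follow-up tissue NGS under
LB-first, or the PD-L1 pathway once tissue NGS is also negative. PD-L1 is
measurable on tissue only, with near-gold-standard performance (0.99/0.99),
and is dichotomised for misclassification as TPS ≥ 50 versus not: a
false-negative TPS ≥ 50 patient is treated in the TPS 1–49
(chemo-immunotherapy) context, a false positive in the TPS ≥ 50 context.
We chose the sequential-panel construction over restricting false positives
to no-driver patients because it reproduces the published per-subgroup
expected diagnostic costs of the LB-first strategy (which encode the
probability of a negative LB panel) to within ~0.5%.

**Survival.** Each terminal branch is linked to a Weibull
progression-free/overall survival pair for the therapy its observed result
triggers. Published parameters are a log-scale and a shape estimate per
context. The package evaluates
\(S(t) = \exp\{-(\lambda t)^{k}\}\) with \(\lambda = e^{\text{log-scale}}\),
\(k = e^{\text{shape}}\) (`weibull_form = "rate-power"`). The alternative
reading \(S(t)=\exp\{-\lambda t^{k}\}\) is available (`"ph"`); the default is
the form under which the published parameters imply clinically plausible
survival (about a 27-month median OS on first-line EGFR-targeted therapy) and
which reproduces the published per-subgroup QALY levels more closely.

**Hazard adjustments.** Each branch's hazard is the product of: the subgroup
calibration HR (capturing survival disparities beyond mutation mix; applied
to both strategies by default — applying it only to tissue-informed branches
roughly doubles the incremental QALYs, far from the published results, so
`calibration_scope = "tb-informed"` is a switch, not the default); the
EGFR-therapy adjustment where the assigned therapy is EGFR-targeted; the
turnaround-time (TAT) HR of 0.72 (3-week scenario; 0.90 for 1-week) on
branches whose therapy was triggered by a positive LB result; and a
mismatched-therapy HR when a false test result assigned the wrong therapy.
HRs act proportionally, \(S(t)^{hr}\). An alternative `hr_application =
"rate"` multiplies the Weibull rate instead (the convention the source table
describes for its EGFR adjustment); it slightly improves the Asian QALY gain
but distorts the relative inequality change and is therefore not the
default.

**Partitioned survival.** Pre-progression occupancy is \(\min(PFS, OS)\) at
every time (curve crossings are clamped rather than re-fitted),
post-progression occupancy is the difference, and QALYs weight the two
states by utilities 0.71/0.67 with continuous discounting \(e^{-rt}\),
\(r = 3\%\)/year, integrated by composite trapezoid. Defaults: 20-year
horizon with a weekly step — by then every context's OS is far below 1%, and
halving the step changes QALYs by less than \(10^{-4}\) (tested). Diagnostic
costs accrue undiscounted at time zero under a blended payer mix (67.4%
Medicare / 32.6% commercial); scenario analyses add year-indexed first-line
drug costs over pre-progression time, second-line costs over a published
duration ratio of post-progression time among the 50% not opting for best
supportive care, and annualized disease-management costs. The second-line
duration ratios are published per first-line/second-line drug-class pairing;
we assign each therapy context the ratio of its closest pairing (e.g. 0.692
after PD-L1 monotherapy, 0.365 after chemo-immunotherapy). The published
year-2+ drug rates already taper immunotherapy regimens, so no additional
duration cap is applied by default (`io_cap_years = Inf`).

## Distributional accounting

Per-patient incremental QALYs \(\Delta Q_g\) and costs \(\Delta C_g\) become
per-capita incremental net health benefit with *equally distributed
opportunity costs*:
\[
iNHB_g \;=\; r_g\,\Delta Q_g \;-\;
\frac{\sum_h w_h\, r_h\, \Delta C_h}{\tau},
\]
where \(r_g\) is the lifetime risk of aNSCLC (incidence × life expectancy)
times the 30% insufficient-tissue fraction, \(w_h\) the general-population
shares, and \(\tau\) the opportunity-cost threshold ($150,000/QALY in the
base case). The subtracted term is identical for every subgroup: the health
displaced by spending is assumed to fall uniformly on the general
population. Adding \(iNHB_g\) to the baseline quality-adjusted life
expectancy (QALE) gives the post-intervention general-population health
distribution.

Inequality is summarised two ways, per Monte Carlo draw, across the four
subgroup means:

* **Atkinson** (relative, scale-invariant):
  \(A_\varepsilon = 1 - \left[\sum_g w_g (y_g/\mu)^{1-\varepsilon}\right]^{1/(1-\varepsilon)}\),
  base aversion \(\varepsilon = 11\);
* **Kolm** (absolute, translation-invariant):
  \(K_\alpha = \alpha^{-1}\log \sum_g w_g e^{\alpha(\mu - y_g)}\),
  base aversion \(\alpha = 0.15\).

Patient-level indices use patient-population weights (share × lifetime
risk, normalised); general-population QALE indices use the census shares.
The equally distributed equivalent (EDE) — \(\mu(1-A)\) or \(\mu - K\) — is
the welfare-equivalent uniform health level and supports the trade-off
analysis when average gains and inequality move in opposite directions.
\(\varepsilon = 1\) (the Cobb–Douglas limit) is deliberately unsupported:
the analysis grids never use it.

## Uncertainty propagation

Every uncertain input carries the distribution its published evidence
implies: Dirichlet for prevalence, PD-L1 and test-confusion vectors
(concentration = backing N × proportion; structural zeros stay zero);
bivariate normal for each (log-scale, shape) pair with the published SEs and
correlation; lognormal for hazard ratios, \(\sigma = (\ln hi - \ln lo)/3.92\)
with the point estimate as the median; beta for utilities (moment-matched to
mean and CI-implied SE, with inverted pre/post draws re-ordered rather than
rejected, preserving the draw count) and for the rebiopsy complication
probability; gamma for management costs; fixed rows pass through. One master
seed spawns independent L'Ecuyer substreams keyed by draw index, so any draw
is reproducible in isolation, scenario runs share random numbers (the
3-week and 1-week analyses see identical parameter draws), and results are
a pure function of `(params, n_draws, seed)`. The paper-scale analyses here
use 2,000–5,000 draws; the summaries reported are means and 2.5th/97.5th
percentiles across draws.

## Evidence-synthesis utilities

The survival inputs of such a model are built from published Kaplan-Meier
figures, and the package implements that path so it can be audited and
stress-tested: `reconstruct_pseudo_ipd()` rebuilds patient-level data from a
digitized curve plus numbers-at-risk table (censoring spread uniformly
within risk-table intervals and iterated until the implied at-risk counts
match; events placed at digitization-interval midpoints, which removes a
half-grid-step late bias); `fit_weibull()` wraps a maximum-likelihood fit
reported in the model's parameter convention with observed-information SEs;
`tat_splice_hr()` derives the turnaround-time HR by splicing
best-supportive-care mortality over the waiting period onto on-therapy
mortality thereafter and fitting a proportional-hazards model to pseudo-data
from the two spliced curves; `rescale_hr_loglinear()` converts the 3-week HR
to other TAT differences assuming log-linearity
(\(e^{\ln(0.72)/3} \approx 0.90\) for one week). The actual published curves
behind the shipped parameters are not redistributed; these utilities are
validated on synthetic curves from `simulate_km()`, whose generator draws
Weibull event times with exponential censoring — it emulates digitization
granularity and risk tables but not digitization reading error or
non-independent censoring, so passing round-trips demonstrate correctness of
the reconstruction machinery, not fidelity to any specific trial.

## Numerical and degenerate-input choices

Published probability vectors are stored exactly as printed (rounded to
0.1%, so some sum to 0.999/1.001) and renormalised when a draw is built;
validators accept 0.005 slack on printed vectors and enforce exact
normalisation afterwards. Zero-variance distributions return their point
estimates, making the point-estimate run the exact degenerate limit of the
PSA. Branches with zero probability (e.g. a mutation absent from a
subgroup) are carried but cannot contribute. A draw that fails evaluation
is dropped with a warning; more than 1% failures aborts the run (none occur
under the packaged inputs or jittered variants). `jitter_parameters()`
perturbs positive inputs multiplicatively and renormalises, guaranteeing the
result revalidates — the fuzz harness for the whole pipeline.

## Known limitations

* The supplementary tree figure and equations of the source analysis are not
  available; the tree is reconstructed from the main text plus the published
  cost/outcome tables. Our incremental QALY distribution is uniformly ~0.03
  below the published means (0.18 versus 0.21 pooled) while per-strategy QALY
  levels, diagnostic costs, inequality means and the relative inequality
  change reproduce within a few percent; the residual sits in the
  per-detected-patient OS benefit and is documented rather than tuned away.
* The published claim that >95% of simulations show a QALY gain together
  with a patient-inequality increase is inconsistent with the published
  Atkinson difference interval (−0.00145 to 0.00803), which places well over
  5% of draws below zero; the corresponding Kolm interval is strictly
  positive. This model reproduces exactly that pattern, and the quadrant
  summary therefore reports both indices.
* Subgroups are race/ethnicity only; access, uptake and within-subgroup
  heterogeneity are out of scope, as are adverse-event costs and third-line
  therapy (excluded from the source analysis), general-population background
  mortality caps, and correlations across distinct input rows (none are
  published).
* A command-line wrapper is deliberately absent: the analysis surface is the
  R API (`dcea()`, `summary()`, `dcea_scenarios()`, `write_outputs()`),
  which scripts compose more robustly than a shell interface.

## A small worked run

```{r, eval = FALSE}
fit <- dcea(n_draws = 2000, seed = 1)
summary(fit)
plot(fit, population = "patient")
write_outputs(fit, "dcea-results")
```
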