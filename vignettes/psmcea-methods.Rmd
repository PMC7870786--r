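---
title: "Methods: partitioned-survival cost-effectiveness with screening costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness with screening costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model

`psmcea` evaluates a test-directed oncology treatment strategy against
standard care with a decision tree feeding a three-state partitioned
survival model (PSM). The decision tree is purely a costing device: in the
test-directed strategy every treated patient carries the cost of the
genomic test that identified them (and, in `per_screened` mode, of the
negative tests incurred along the way). The PSM then projects the treated
cohort.

A PSM does not model transitions. State occupancy at cycle time $t$ is
read directly off the two endpoint curves:

$$p_{PFD}(t) = \min\{S_{PFS}(t), S_{OS}(t)\},\qquad
  p_{PD}(t) = S_{OS}(t) - p_{PFD}(t),\qquad
  p_{dead}(t) = 1 - S_{OS}(t).$$

The `min` clamp enforces the logical constraint that no more people are
progression-free than alive; the partition identity
$p_{PFD}+p_{PD}+p_{dead}=1$ then holds by construction and is asserted per
cycle in the test suite. The implicit assumptions are the usual ones:
PFS and OS describe the same cohort, and post-progression survival is not
modelled mechanistically — whatever dependence exists between progression
and death is already baked into the two curves.

Cycles are one week. Costs and QALYs are discounted at 3% per year with
the exact week-fraction exponent $(1+r)^{-w/52.1775}$. Curve parameters
are on a months scale (trial medians are reported in months) and the
engine converts with $1\ \mathrm{month} = 365.25/84$ weeks. No half-cycle
correction is applied by default — the source analysis is silent on it
and at one-week cycles the discretization error is far below every other
uncertainty in the model; a `half_cycle` flag exists.

## Survival machinery

Ten families are supported (see `?surv_dist`). Parameterizations follow
the published input-table labels: gamma and Gompertz use (shape, rate),
Weibull uses the `stats` (shape, scale) convention with `rate = 1/scale`
accepted, log-logistic uses $S(t) = 1/(1+(t/s)^a)$ so the median equals
the scale. The Royston–Parmar model writes the log cumulative hazard as a
restricted cubic spline in $\log t$; with four coefficients
$\gamma_0..\gamma_3$ this means two internal plus two boundary knots.
Cure models come in mixture form $S(t)=\theta+(1-\theta)S_u(t)$ and
non-mixture form $S(t)=\theta^{1-S_u(t)}$, where $\theta$ is the cured
fraction.

Two published-input ambiguities are surfaced rather than guessed away:

- **Scale convention.** The printed log-logistic/cure "scale" values are
  inconsistent with the trial's medians if read as months on the natural
  scale (a log-logistic scale of 2.889 implies a 2.9-month median against
  a reported 7.4 months; read as $e^{2.889} \approx 18$ months it is too
  long). `surv_dist(..., scale_on_log = TRUE)` makes both readings
  available; the natural scale is the default.
- **Spline knots.** The published spline coefficients come without knot
  locations and are not evaluable without them. The fixture
  configurations carry deliberately narrow placeholder knot spans, chosen
  so that the printed coefficients yield a monotone cumulative hazard
  (the spline basis is linear beyond the boundary knots, so a narrow span
  bounds the cubic terms); the resulting curves are mechanically valid
  but not a reconstruction of the originals. When *fitting* a spline
  model, default knots sit at the extreme uncensored log event times
  (boundary) and the 33rd/67th centiles (internal).

Fitting maximizes the right-censored log-likelihood
$\sum_{events}\log f(t_i) + \sum_{cens}\log S(t_i)$ by BFGS on
unconstrained transforms (log for positive parameters, logit for
$\theta$). Cure-model likelihoods can be multimodal, so each fit runs a
deterministic ladder of five transformed-scale start offsets
$\{0,\pm0.5,\pm1\}$ and keeps the best optimum — deterministic by design,
so that the only random seed in the package is the user's. Convergence
uses `optim`'s relative tolerance at `1e-10`; non-converged fits are
flagged and excluded from AIC selection. Model selection is minimum AIC
($2k-2\ell$, asserted exactly in tests) with ties broken toward fewer
parameters.

## Pseudo-IPD reconstruction

Published Kaplan–Meier figures plus numbers-at-risk are converted to
virtual patient records with the Guyot-style interval algorithm: within
each interval between risk-table times, the censored count is solved
iteratively so that, with censoring spread uniformly across the interval
and events placed at the digitized step times (chosen to match each
digitized survival drop), the reconstructed risk set equals the published
one at the next risk time. Within the final interval (and whenever no
risk table exists, with a warning) censoring is assumed administrative at
the end of follow-up. Infeasible intervals (implied negative counts) are
clamped at zero. The procedure is fully deterministic; a published total
event count, when supplied, rescales the reconstructed events.

The qualitative claim that reconstruction "closely reproduces" the
digitized curves is operationalized as: maximum absolute deviation
between the original and reconstructed Kaplan–Meier curves at the
digitized times $\le 0.02$, checked over 20 simulated scenarios spanning
sample sizes 80–600 and four curve shapes. `survival::survfit()` serves
as the independent Kaplan–Meier oracle in these round trips; the
reconstruction itself never calls it.

## Tail extrapolation

The intervention arm's follow-up is shorter and less mature than the
comparator's, so beyond the observed cutoffs (defaults: 18 months for
PFS, 24 for OS) the engine switches to a proportional-hazards
carry-forward of the comparator curve:

$$S(t) = S_{own}(c)\,\bigl(S_{ref}(t)/S_{ref}(c)\bigr)^{HR},\quad t > c,$$

which is continuous at $c$ and inherits the comparator's shape scaled by
the hazard ratio. `adjusted_survival()` errors when $S_{ref}(c)=0$
(nothing left to extrapolate); the engine degrades gracefully in that
case — it warns and keeps the arm's own curve — because fixture
configurations with placeholder spline knots can legitimately exhaust the
reference curve early, and a base-case run should not die on an input the
configuration explicitly flags as a placeholder.

## Costs and QALYs

Per cycle, discounted:

- **PFD**: first-line drug acquisition (weekly cost net of the 15%
  contract-price discount; a `drug_cost_is_discounted` switch controls
  whether listed costs are read as pre- or post-discount, since the
  source is ambiguous) plus follow-up, times PFD occupancy. Standard-care
  drug cost is the 54%/46% enzalutamide/abiraterone mix.
- **PD**: the fraction `p_subsequent_active` of *new progressors* incurs
  a lump subsequent-therapy cost (regimen-mix monthly cost × duration) at
  progression; a cohort engine cannot track per-patient time since
  progression, and the lump is the standard workaround — undiscounted it
  is exactly equivalent to accruing the regimen over its duration, and at
  3%/year the difference is negligible. The non-active fraction accrues
  daily supportive care while in PD; everyone alive accrues follow-up.
- **Death**: a one-off terminal-care cost per new death, at the cycle of
  death.
- **Cycle 1**: adverse-event management costs and duration-weighted
  AE disutilities (probability × disutility × weeks/52.1775), applied
  once — the source applies all AEs in the first cycle. AE incidence
  rates are not published, so fixtures default them to zero and the
  engine's AE path is exercised with synthetic fixtures in tests.
- **Cycle 0**: the NGS screening cost for the test-directed arm, either
  flat ($5,800 per treated patient — the reading required for the
  published totals to be arithmetically possible) or
  `test_cost × NNS(prevalence)` with `NNS = 1/prevalence` rounded to one
  decimal (5.6 at 18%), which reproduces the published
  number-needed-to-screen argument.

"Cost in the PFD state" in reports aggregates drug, PFD follow-up, AE and
screening costs, matching how the published table attributes the NGS cost
to the PFD column.

The time horizon is not stated in the source; the default is 520 weeks
(10 years), by which time state occupancies under any plausible mCRPC
curve are a fraction of a percent. It is configurable, and several test
paths shorten it purely for speed.

## Decision metrics

`evaluate_ce()` computes $ICER = \Delta C/\Delta E$,
$INHB(\lambda)=\Delta E-\Delta C/\lambda$ and
$INMB(\lambda)=\Delta E\cdot\lambda-\Delta C$ (identically
$\lambda\cdot INHB$). ICERs are reported only in quadrants I/III of the
CE plane; quadrant II is "dominant", IV "dominated". The
cost-effectiveness flag is $INMB>0$, which coincides with
"ICER < $\lambda$ or dominant" in quadrants I/II and handles quadrant III
correctly (a saving per QALY lost must *exceed* $\lambda$ to be
worthwhile). Report rounding matches the published precision: whole
dollars, three decimals for (QA)LYs and INHB.

## Uncertainty analysis

**Derivation rules.** Ranges are read as 95% intervals,
$sd=(high-low)/3.92$. Beta parameters use
$total=m(1-m)/sd^2$, $\alpha=m\cdot total$ — deliberately *without* the
usual $-1$ correction, because that is the convention the published
input table was built with (it reproduces the printed PD-utility pair
$\alpha=207.1,\beta=352.6$ exactly; with the $-1$ it does not). Gamma
uses method of moments on (shape, scale); printed $(\alpha,\beta)$ pairs
are accepted as overrides interpreted with mean $\alpha\beta$. Hazard
ratios use $\mu=\log(point)$, $\sigma=\log(high/low)/3.92$; the printed
log-sd values (2.88 and friends) are inconsistent with any CI-based
derivation and would make the PSA explode, so the CI-based $\sigma$ is
the default and printed values remain available as explicit overrides.
The printed beta pairs for the subsequent-treatment proportions likewise
do not follow the utility rows' derivation and are used as overrides
only.

**One-way analysis** re-runs the model at each parameter's bounds
(default: ±25% when no range is given) and sorts by outcome span. The
outcome metric is INHB: the source's tornado is not explicit about its
metric, but its results discussion is phrased in INHB break-even terms.
The first-line intervention drug price is sampled as fixed in the PSA
(per its "Fixed" distribution entry) but varied in one-way analysis over
half to full price.

**PSA** draws all parameters jointly and independently (the source
samples independently), re-runs the model per iteration, redraws
out-of-support values with a logged count, and is reproducible from a
single seed. The CEAC reports, per $\lambda$, the fraction of iterations
with $INMB(\lambda)>0$ (default grid $0$–$300{,}000$ in $5{,}000$
steps). **Subgroup analysis** varies the PFS hazard ratio: deterministic
INHB at the subgroup point estimate and CI limits, plus the PSA
probability of cost-effectiveness with the PFS HR resampled from the
subgroup's log-normal.

## Synthetic data

The generator emulates what the original analysis digitized: arm-level
time-to-event data under configurable distributions with administrative
censoring, and "digitized" curve coordinates with risk tables. Overall
survival is built as progression time plus an independent
post-progression residual, which guarantees PFS ≤ OS patient-wise — the
constraint the PSM clamp assumes; a copula for stronger dependence is out
of scope. Digitization is exact by default (`jitter = 0`) so round-trip
tolerances are attributable to the reconstruction alone; optional
Gaussian jitter (clamped and re-monotonized) mimics digitization error.

What a green test therefore establishes: the machinery — fitting,
selection, reconstruction, accrual, uncertainty propagation — is
internally consistent and recovers known truths from data generated under
its own assumptions. What it does not establish: fidelity to any real
trial's curves (no coordinates are published to digitize), or
reproduction of the published base-case totals.

## Why the published totals are not a target

Four required inputs are unpublished (time horizon, spline knots, AE
incidences, subsequent-therapy mix and duration), and the published
life-year totals (0.221–0.665 years) are internally inconsistent with the
trial's median survivals (12–19 months), so no choice of the missing
inputs can reconcile them. The published *increment arithmetic* is
reproducible and is what the acceptance suite asserts: scenario-B INHB of
0.114 QALYs from the printed increments ($\Delta E = 0.068$,
$\Delta C=-\$6{,}950$, $\lambda=\$150{,}000$), the $1,980 PFD-cost
increment and $6,950 saving from the published per-arm cells, life-year
increments of 0.100 and 0.125, and NNS = 5.6 at 18% prevalence. Where the
source contradicts itself (abstract's "$1,980 saved" vs the results
table's $6,950 saving), the results table is taken as authoritative.

## Other conventions and limitations

- Configurations serialize as JSON (one field per published input row);
  run artifacts are CSV with a JSON sidecar carrying the seed and an MD5
  configuration hash.
- Currency is 2019 USD throughout; no inflation adjustment happens inside
  the engine.
- Left truncation, interval censoring, covariate-adjusted survival
  models, Bayesian fitting, treatment-switching adjustment, efficiency
  frontiers with more than two comparators and budget impact are all out
  of scope.
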