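---
title: "Methods: the D50 model and MUNIX time-to-threshold biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the D50 model and MUNIX time-to-threshold biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munixd50)
```

# The disease-progression model

ALSFRS-R totals (0–48, higher = better function) decline from near-full
function through an accelerating phase to a low plateau. We model each
patient's trajectory as a logistic decay

$$\mathrm{ALSFRS\mbox{-}R}(t) = \frac{48}{1 + e^{(t - D_{50})/d_x}},$$

with $t$ in months since symptom onset. This is the unique standard
sigmoid consistent with a 48-point full scale and a turning point at half
function (score 24) at $t = D_{50}$. $d_x$ sets the steepness of the
collapse around $D_{50}$ and is reported but not interpreted clinically
here. Assumptions worth stating: the decline is monotone (no sustained
recovery), starts from the full score at onset, and a single sigmoid
describes the whole observed course. Plateaus from bulbar-onset sparing of
limb function, treatment effects, or measurement floors in subscores are
absorbed into the residuals.

The accumulation coordinate is $rD_{50} = t/(2 D_{50})$: 0 at onset, 0.5
at $D_{50}$, linear in between — the only linear scale through those two
anchors. Phases are half-open intervals: I $[0, 0.25)$, II $[0.25, 0.5)$,
III/IV $[0.5, \infty)$; aggressiveness subgroups likewise: high
$[0, 20)$, intermediate $[20, 40)$, low $[40, \infty)$ months. Boundary
values therefore classify upward (e.g. $rD_{50} = 0.25$ is Phase II,
$D_{50} = 20$ intermediate).

## Fitting numerics

`fit_d50()` minimizes the residual sum of squares with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`), $D_{50} \in [0.1, 600]$,
$d_x \in [0.1, 120]$ months. Initialization: $D_{50}^{(0)}$ at the first
downward crossing of 24 on the piecewise-linear interpolation of the
observations (fallback: last observation time); $d_x^{(0)}$ at a quarter
of the observation span. The RSS surface has a family of step-function
local minima ($d_x \to$ lower bound, the sigmoid degenerating to a step
between two visits), which single-start fits fall into on steep
trajectories; we therefore multi-start over $D_{50}^{(0)} \times
\{1, 0.5, 1.5, 0.75, 1.25\}$ and $d_x^{(0)} \times \{1, 1/4, 1/16\}$,
keep the lowest RSS, and stop early only when the fit is numerically
exact. Tolerances are set tight (`ftol = ptol = 1e-14`) because the
noiseless-recovery contract is relative error below $10^{-6}$; observed
recovery on exact trajectories is at machine precision.

Two observations are the minimum (two parameters, exact interpolation);
series whose scores never decrease carry no information about a decay
curve and are flagged `identifiable = FALSE` and routed to the exclusion
ledger rather than silently fitted.

# The MUNIX time-to-threshold biomarkers

The three-muscle sums (APB + ADM + TA) of MUNIX, CMAP and MUSIX
(= CMAP in µV / MUNIX, per muscle, summed) are referenced to the
healthy-control mean sums, which define 100%. With observed ratio $r$ at
measurement time $t_{obs}$, the time to a target level $g$ under a linear
trajectory anchored at 100% at onset is

$$\hat t(g) = t_{obs} \, \frac{1 - g}{1 - r},$$

giving M50 and CMAP50 at $g = 1/2$ and MUSIX200 at $g = 2$. Longitudinal
MUNIX studies support approximate linearity over the observed disease
course, which is what justifies a single-measurement extrapolation.

Design choices made explicit:

* **Anchoring at onset.** The line passes through ratio 1.0 at $t = 0$.
  Nothing else is identifiable from a single measurement, and it matches
  the convention that the control level is "100%" and all times are
  onset-anchored. The known cost: motor units already lost before symptom
  onset are invisible, so M50 is a lower-bound-flavoured estimate.
* **Sum-based aggregation for all three metrics.** MUSIX200 and CMAP50
  are computed on three-muscle sums relative to the control mean sum,
  mirroring M50; the control MUSIX baseline is the mean over controls of
  their per-control MUSIX sums (equivalently the sum of per-muscle mean
  MUSIX), not the quotient of the mean CMAP and MUNIX sums — the two
  differ slightly because the mean of quotients is not the quotient of
  means.
* **Undefined is a status, not an error.** A patient at or above the
  control level has no M50/CMAP50 (`no_decrease`); at or below, no
  MUSIX200 (`no_increase`). Cohort summaries report per-metric defined
  $n$, and such patients drop out of that metric's analyses only.
* **Floors before ratios.** Muscles with no obtainable signal, or with
  CMAP at or below the 0.5 mV guideline bound, enter the sums at MUNIX 2,
  CMAP 0.5 mV, MUSIX 250 (= 500/2). Including floored patients avoids the
  survivor bias of dropping advanced disease.

# Exclusion rules

`apply_exclusions()` applies, in order, first match wins: (1) Gold Coast
criteria not fulfilled; (2) measurement on the more affected side;
(3) fewer than two ALSFRS-R questionnaires; (4) juvenile ALS; (5) MUNIX
sum at or above the control mean (M50 undefined); (6) M50 beyond plausible
life expectancy; (7) non-identifiable D50 fit. The life-expectancy cutoff
is not a published constant; we project onset age plus M50 and exclude
beyond 100 years when age is available, else apply an absolute cap of
720 months (60 years of disease), both configurable. The ledger is
conservative by construction: every input patient is either retained or
counted under exactly one rule.

# Statistical conventions

Medians and IQRs use linear interpolation between order statistics
(`quantile` type 7). Median splits send ties at the cutoff to the high
group (the low group is "under" the median). Kruskal–Wallis uses the
tie-corrected H with the $\chi^2$ approximation (subgroup sizes here make
exact enumeration pointless); pairwise post-hocs are two-group rank tests
with Bonferroni factor 3, capped at 1. Survival uses the product-limit
estimator and the two-sample log-rank $\chi^2$ (via the survival package);
the KM median is the smallest time with $S(t) \le 0.5$. Survival time is
measured from symptom onset, consistent with every other time in the
package; this choice matters when comparing absolute medians across
studies that start the clock at diagnosis.

# What the synthetic cohorts emulate

`generator_config()` defaults are the study conditions the analysis
assumes:

* cohort of 222 patients mixed over aggressiveness subgroups with weights
  64/92/66, true $D_{50}$ drawn per subgroup from log-normals centred on
  medians 13.8 / 28.0 / 61.5 months (sdlog 0.35) and truncated at the
  subgroup boundaries so labels hold by construction;
* visits every 2.8 months on average (SD 0.9, first visit 2–6 months),
  additive ALSFRS-R noise SD 2 points, rounded and clamped to the 0–48
  integer scale;
* controls: per-muscle MUNIX normals truncated at zero with means/SDs
  APB 168.6/58.6, ADM 154.4/40.2, TA 137.2/28.9; control CMAP means
  APB 10.5, ADM 11.0, TA 6.0 mV (SDs 2.5/2.5/1.8) — the MUNIX moments are
  reference values for these muscles, the CMAP moments are chosen from
  normative electrophysiology ranges since no control CMAP table is
  published alongside them;
* linear MUNIX decline whose sum crosses 50% of the control mean exactly
  at true M50 $= 0.5 \cdot D_{50}$; CMAP analogous with factor 0.62
  (matching the relative spacing of the observed cohort medians of M50,
  CMAP50 and $D_{50}$); per-muscle values split proportionally to the
  control means with multiplicative log-normal noise (sdlog 0.2).
  Because the panel schema carries only MUNIX and CMAP, MUSIX is the
  induced quotient; its doubling time is implied, not dialled, and is
  recorded in `truth.csv`;
* measurement time at $rD_{50} \sim N(0.30, 0.10)$ truncated to
  $[0.05, 0.60]$ — the cross-sectional sampling shift that makes
  aggressive patients present later on the accumulation clock;
* survival $= 1.8 \cdot D_{50} \cdot e^{\varepsilon}$, $\varepsilon \sim
  N(0, 0.3)$, 25% censored; 2% of muscles unobtainable.

Per-patient randomness uses counter-derived sub-seeds from the master
seed, so enlarging a cohort extends it without reshuffling existing
patients, and identical seeds give byte-identical CSVs.

`noiseless_config()` is the deterministic limit used for exact-recovery
checks: all noise SDs zero — including the control SDs, so the sampled
control means equal the configured means exactly — scores unrounded,
no unobtainable muscles, and measurement inside $rD_{50} \in [0.1, 0.45]$
where no floor can trigger. Under it the pipeline recovers every true
$D_{50}$ (relative error $< 10^{-6}$) and true M50 ($< 10^{-9}$). The
score validator consequently checks only the 0–48 range, not
integrality, so model-smoothed trajectories pass through the same I/O
path.

What the generator does **not** emulate: per-muscle heterogeneity of
decline (bulbar vs limb onset patterns), non-linear or pre-symptomatic
MUNIX kinetics, correlated measurement error between muscles, informative
censoring, or any EMG-level physics. Passing tests on synthetic cohorts
therefore demonstrate that the estimators recover the quantities the data
generating process defines — not that real ALS data satisfy the linearity
or sigmoid assumptions.

# Problem sizes

The shipped tests use cohorts of 20–222 patients, 200 trajectories for
parameter-recovery sweeps, 1,000 random inputs for the closed-form vs
line-stepping oracle comparison, ten seeds at the full cohort size of 222
for the M50/$D_{50}$ ratio property, and 100,000 simulated controls for
calibration of the control generator; the full suite runs in well under a
minute on one core.

# Known limitations

Single-measurement linear extrapolation inherits all the caveats above;
M50 and friends are undefined for patients without decline (under 5% in
realistic settings, but structurally missing, not at random); the D50 fit
assumes the full score at onset, biasing $D_{50}$ upward for patients
with pre-onset functional loss; and the KM median confidence intervals
are not implemented (medians only), as subgroup comparison here rests on
the log-rank test.
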