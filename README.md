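# munixd50

Disease-progression modelling for amyotrophic lateral sclerosis (ALS)
combining the **D50 model** of functional decline with **MUNIX-based
electrophysiological biomarkers**.

ALS progresses at wildly different speeds between patients, and a single
cross-sectional measurement mixes up *how aggressive* the disease is with
*how far along* it is. This package implements two complementary answers:

1. **The D50 model.** Each patient's longitudinal ALSFRS-R totals (revised
   ALS Functional Rating Scale, 0–48 points) are fit with an individual
   sigmoidal decay curve

   ```
   ALSFRS-R(t) = 48 / (1 + exp((t − D50) / dx))
   ```

   where `t` is months since symptom onset. **D50** — the turning point,
   where the predicted score is exactly 24 — is the time to lose 50% of
   full motor function (disease *aggressiveness*; cohorts stratify into
   high `D50 < 20`, intermediate `20 ≤ D50 < 40`, low `D50 ≥ 40`).
   **rD50** `= t / (2·D50)` is a normalized disease-accumulation clock
   (0 at onset, 0.5 at D50) with Phases I (`< 0.25`), II (`0.25–0.5`) and
   III/IV (`≥ 0.5`).

2. **M50, CMAP50, MUSIX200.** From one three-muscle panel (APB, ADM, TA)
   of motor unit number index (MUNIX) and compound muscle action potential
   (CMAP) values, measured at disease duration `t_obs`, each sum score is
   expressed as a ratio `r` to the healthy-control mean sum (the 100% base
   level) and extrapolated linearly from 100% at symptom onset:

   ```
   time to target g  =  t_obs · (1 − g) / (1 − r)
   ```

   with `g = 0.5` for **M50** (months until the MUNIX sum halves the
   control level) and **CMAP50**, and `g = 2` for **MUSIX200** (months
   until the motor unit size index, MUSIX = CMAP(µV)/MUNIX, doubles —
   a reinnervation marker). Muscles with no obtainable signal
   (CMAP ≤ 0.5 mV) enter at fixed floor values (MUNIX 2, CMAP 0.5 mV,
   MUSIX 250) so that advanced patients are not silently dropped.

On top sit the cohort analyses: exclusion rules with an auditable ledger,
median/IQR summaries per aggressiveness subgroup and rD50 phase,
Kruskal–Wallis tests with pairwise Bonferroni post-hocs, Spearman
correlations, median-split Kaplan–Meier survival with log-rank tests, and
M50/D50 "separation group" classification. Because real patient-level data
of this kind are not public, a seeded synthetic-cohort generator emulates
the assumed data structure (sigmoid ALSFRS-R decay, ~2.8-month visit
cadence, linear MUNIX decline crossing 50% at a known true M50,
D50-coupled survival) so that every pipeline stage is testable against
known ground truth.

## Worked example

```r
library(munixd50)

# one patient: five ALSFRS-R assessments
fit <- fit_d50(c(2.1, 5.3, 8.2, 11.0, 14.4), c(46, 44, 40, 35, 28))
fit
#> D50 model fit: D50 = 15.83 months (high aggressiveness), dx = 4.62
#>   n = 5 observations, RSS = 0.7644, converged: TRUE

# a full synthetic study: simulate, fit, exclude, derive biomarkers, report
res <- run_study(generator = generator_config(), seed = 1, out_dir = "demo")
res$ledger
#> Exclusion ledger: 222 in, 220 retained
#>   no_munix_decrease      2
res$report
#> Cohort report: 220 patients
#>   high aggressiveness (n = 67): M50 6.9, D50 13.4 months
#>   intermediate aggressiveness (n = 92): M50 13.6, D50 27.1 months
#>   low aggressiveness (n = 61): M50 32.7, D50 61.1 months
#>   KM median survival by M50 split: low 33, high 89 months
```

Two of 222 simulated patients happened to sit above the control MUNIX
level (no decrease, M50 undefined) and were excluded, mirroring how such
patients are handled in practice. M50 medians rise steeply across the
aggressiveness subgroups while staying at about half of D50 — motor unit
loss reaching the 50% level roughly one half-course ahead of clinical
function — and a low M50 identifies the short-survival half of the cohort
(33 vs 89 months median survival). `run_study()` also writes
`d50_fits.csv`, `patient_metrics.csv`, `cohort_report.json`,
`survival_summary.csv`, `exclusion_ledger.json` and `run_manifest.json`
to `out_dir`.

A command-line front end ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/munixd50", package="munixd50"))')" \
  run --simulate --out demo --seed 1
```

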