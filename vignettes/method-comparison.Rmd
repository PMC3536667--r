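---
title: "Comparing self-reported and sensor-measured physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing self-reported and sensor-measured physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actagree)
```

## The measurement problem

Free-living physical activity can be asked about or measured. A
domain-specific computerized questionnaire asks a respondent to recall a
usual week — sitting, bouted moderate and vigorous activity, occupation,
sports, screen time, household chores, transport, eating and sleeping —
and converts the answers into weekly parameters using fixed MET
(metabolic equivalent of task) intensities from a published compendium.
A multi-sensor armband worn around the clock produces a minute-by-minute
MET stream; synchronized with an electronic activity diary it yields the
*same* parameters from an objective record. Neither instrument is a gold
standard: self-report suffers recall and social-desirability bias, and
the monitor compresses very vigorous intensities and cannot say *what*
the wearer was doing. The interesting quantity is therefore their
*agreement*, parameter by parameter, and how it varies with gender and
age.

`actagree` implements both measurement paths, the agreement statistics,
and a synthetic-cohort generator that stands in for raw study data.

## The twenty parameters

Both paths produce an `activity_profile` with, per week: PAL (mean MET
over 168 h), total energy expenditure (METh), bouted moderate and
vigorous activity (h), sedentary time (h), and time/energy pairs for
job, sports, screen (time only), household chores, active transport,
motorized transport, eating and sleeping.

Questionnaire scoring follows the instrument's arithmetic exactly:

* daily questions (sitting, screen, leisure transport) are expanded to a
  week as `weekday × 5 + weekend-day × 2`;
* bouted moderate/vigorous activity is `days × hours-per-day`;
* occupational EE splits weekly hours into light/moderate/vigorous
  fractions at 2/3/4 MET; household chores use 2.5/3.5/4.5 MET; active
  transport 4 MET; motorized transport 1.5 MET; eating 1.8 MET; sleep
  0.9 MET; sports use per-sport compendium METs with in-season hours
  annualized over twelve months;
* total EE adds the seven domain EEs and scores the *residual* leisure
  time — 168 h minus the seven time-accounted domains — at 1.5 MET.
  Screen time is deliberately absent from the residual subtraction,
  mirroring the instrument's printed formula: screen hours overlap
  sitting and are not a time-accounting domain. PAL is total EE / 168.

Fusion of the sensor stream with the diary applies, in order: non-wear
imputation (sleep minutes get the subject's mean observed sleeping MET;
personal care 2 MET; swimming 6 MET — the armband comes off in water),
wear-time validation (a valid day has ≥ 1368 min of data, i.e. 95% of
24 h; a valid subject has ≥ 6 valid days including Saturday and Sunday),
bout detection (runs of ≥ 10 consecutive minutes with MET in [3, 6) or
[6, ∞)), sedentary time (minutes ≤ 1.8 MET outside diary sleep), and
diary-guided domain aggregation (time from interval lengths, EE from the
minute MET sums). Subjects with exactly six valid days are extrapolated
to a week as `mean(4 valid weekdays) × 5 + Saturday + Sunday`.

## Numerical and design choices

Several points are underdetermined by the instruments' published
descriptions; the package resolves them as follows.

* **Banded answers.** The questionnaire presents many items as ordered
  response bands. Their numeric conversion is shipped as a data table
  (`response_bands()`), valued at band midpoints with open-ended top
  bands at their stated bound. Because it is data, a different
  convention can be supplied without touching the scorer.
* **Over-reported weeks.** Reported domain times can exceed 168 h; the
  residual-leisure term is then clamped at zero with a warning
  (`clamp_residual = TRUE`), or the record rejected in strict mode. The
  warning preserves the audit trail without discarding the subject.
* **Bout strictness.** A bout ends at the first sub-threshold or missing
  minute; no tolerance minutes are allowed. This is the conservative
  reading of "at least 10 consecutive minutes" and is what the
  brute-force oracle in the test suite verifies.
* **Bouts across midnight** are detected on the continuous week-long
  series: the definition is intensity-based, not day-based. Day
  *validity*, by contrast, is counted per calendar day.
* **Sleep in the sedentary definition** means diary-labelled
  sleeping/resting minutes — the diary is the only sleep source in the
  pipeline.
* **Imputed minutes** carry MET values like any other minute, so
  personal-care and swimming imputations can in principle contribute to
  intensity classes; with their constants (2 and 6 MET) only swimming
  reaches the vigorous band.
* **Uncovered minutes** (worn, but no diary entry) are allowed in
  lenient mode: they enter totals and intensity classes but no domain,
  which keeps the conservation identity — domain sums plus the
  uncategorized remainder equal the week totals — testable. Strict mode
  rejects them.
* **Unbalanced subgroup ANOVA** uses Type III sums of squares with
  sum-to-zero contrasts (via `car::Anova`); Tukey HSD across age groups
  runs only when the age main effect is significant at 0.05. No
  multiple-testing correction is applied across the twenty parameters —
  each is tested at 0.05, matching the convention of the comparison
  literature this package serves; `p.adjust` can be applied downstream.
  The 1.96 multiplier for the limits of agreement is the classical
  fixed value, not a *t* quantile.

## What the generator emulates — and what it does not

`generate_subject()` draws a latent weekly schedule: integer-minute
intervals covering all 10080 minutes of a Monday-to-Sunday week, with
sleep split around midnight, weekday job blocks at a per-subject
light/moderate/vigorous mix, commuting by one mode, household chores
concentrated in the weekend, up to two sports, meals, screen time and a
flexible "other leisure" filler. Each interval carries a true MET equal
to the compendium constant the questionnaire would assign it (job 2/3/4,
chores 2.5/3.5/4.5, walking and cycling 4, motorized 1.5, eating 1.8,
sleep 0.9, and 1.5 for the residual categories including personal care
and screen). This choice is deliberate: it makes the latent energy truth
*common* to both instruments, so that with an unbiased reporter, a
noiseless sensor and banding off, the questionnaire score and the fused
profile agree exactly on all twenty parameters — the pipeline's
strongest end-to-end invariant, tested to 1e-6.

The two observation models then separate the instruments:

* the **bias model** multiplies recalled durations (vigorous up,
  moderate/sitting/chores/motorized down, job slightly up), shifts
  reported occupational intensity upward, adds lognormal recall noise
  and optionally snaps answers to response bands. The
  `reporting_bias_reference()` preset fixes the magnitudes at the mean
  ratios observed in a published comparison cohort of 442 adults
  (e.g. vigorous ≈ 3.4×, moderate ≈ 0.32×, sitting ≈ 0.60×);
* the **sensor model** adds truncated Gaussian minute noise, compresses
  MET above 6 by a configurable factor, and inserts non-wear episodes
  whose minutes are later imputed or lost — so some simulated subjects
  genuinely fail wear-time validation, as in a real cohort.

What the generator does **not** emulate: day-to-day autocorrelation
beyond the weekday/weekend split, seasonal sports (in-season months are
fixed at twelve so that the monitored week *is* a usual week),
simultaneous activities (the diary forces single categories; the real
questionnaire lets screen time overlap sitting), demographic activity
gradients, and any fitting of the bias model to real raw data (which is
unavailable). Passing tests therefore demonstrate the *pipeline's*
correctness and the qualitative reproduction of published discrepancy
directions, not a calibrated reconstruction of any real cohort.

## Problem sizes and reproducibility

The test suite and the acceptance script use: ≥ 1000 random fixtures per
brute-force oracle comparison; five to six subjects for exact loop
closure; replicate cohorts of n = 200 subjects (100 replicates in the
sign-pattern test) for cohort-level direction checks; and 1000
replications of n = 500 Normal pairs for the paired-t size and
Bland-Altman coverage calibration. These sizes give Monte-Carlo errors
comfortably below the tested margins. All randomness flows from explicit
seeds; cohorts derive per-subject seeds from the master seed by counter,
so they are reproducible and order-independent.

## A worked example

```{r, eval = FALSE}
cfg <- reporting_bias_reference()
cohort <- generate_cohort(200, cfg, seed = 1)
pc <- profile_cohort(cohort)               # drops wear-time-invalid subjects
head(difference_table(pc))                 # Table-style comparison
bland_altman(pc$fpacq$total_ee, pc$swd$total_ee)
subgroup_anova(pc, "vigorous_pa")          # gender x age on difference scores
```

## Known limitations

The scorer implements one questionnaire variant (employed/unemployed
adults, ages 20–64); student and pensioner variants are out of scope, as
are raw sensor decoding and the manufacturer's proprietary EE algorithm
(the minute MET stream is an input). The shipped sports compendium is a
small subset — unknown sports need an explicit MET value. The
reference-means table reproduces published group-level arithmetic only;
subject-level statistics of that cohort (correlations, p-values) depend
on raw data that was never deposited and are not reproducible here.
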