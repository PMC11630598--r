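---
title: "A lifetime Markov cost-utility model of bariatric surgery in obesity with T2DM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cost-utility model of bariatric surgery in obesity with T2DM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bariaCEA)
```

## The decision problem

`bariaCEA` models the lifetime costs and health outcomes of laparoscopic
bariatric surgery against usual (non-surgical) care for patients with
obesity (BMI ≥ 32.5 kg/m²) and type 2 diabetes mellitus (T2DM) who have not
yet developed macro- or microvascular complications, in the Thai health
system. The clinical premise is that surgery sharply raises the probability
of diabetes remission in the first years after the operation, and remission
both improves quality of life (utility 0.97 vs 0.83) and lowers annual
treatment and care costs, at the price of a large one-time operative cost
(≈ 280,000 baht including preoperative management).

The model answers three questions: the incremental cost-effectiveness ratio
(ICER, baht per quality-adjusted life year) under a payer and a societal
perspective; the robustness of that ICER to parameter uncertainty (one-way
and probabilistic sensitivity analysis); and the five-year national budget
impact of funding the surgery for the eligible population.

## Model structure

The engine is a Markov cohort model with a one-year cycle and eight states:

* `OBESE_T2DM` — obese with T2DM, no complication (the entry state);
* `REMISSION` — diabetes remission without complication;
* `MI_FIRST_YEAR` / `MI_POST` — myocardial infarction, split into a
  one-cycle tunnel so the much higher first-year MI treatment cost
  (119,212 vs 28,613 baht/year) attaches only to the incident year;
* `STROKE`, `CHF`, `CKD` — stroke, congestive heart failure, chronic
  kidney disease;
* `DEAD` — absorbing.

Clinically this is a seven-state model; the MI tunnel is an accounting
refinement. Complication states are absorbing apart from death: only the
first complication is modelled, and there are no transitions between
complications.

Transitions out of `OBESE_T2DM` are remission (cycle-indexed in the surgery
arm: 0.4333, 0.2941, 0.0833 in cycles 1–3 and 0.0156 from cycle 4 onward,
the non-surgical value), four annual complication risks, and background
death; the residual mass stays. The whole surgical cohort is operated once
at cycle 0, so years since surgery and cycle index coincide, and after a
relapse the cycle-indexed (not time-in-state) remission probability applies
— by cycle 4 the two are identical anyway. Remission carries arm-specific
relapse probabilities (0.0107 surgery, 0.0708 non-surgery) and slightly
lower complication risks.

### Mortality

Background mortality is an age-specific annual death probability `q(age)`
from a life table, multiplied by a rate ratio `RR` for the excess mortality
of obesity with T2DM and capped at 1. Remission is assumed not to change
all-cause mortality, so the same adjusted probability applies in both
living pre-complication states. In complication states the annual
state-specific case fatality (MI 0.032, stroke 0.0494, CHF 0.325, CKD
0.1098) is combined with background mortality as independent competing
risks, `1 − (1−p)(1−q)`. Whether the original analysis combined them
additively, multiplicatively or by replacement is not stated; the
multiplicative rule is this package's choice because it never produces a
probability above 1 and does not double-count deaths.

Two inputs of the original analysis are not publicly available: the
national life table and the numeric mortality RR. The package therefore
ships a synthetic Gompertz life table, `q(age) = min(1, a·e^{b·age})` with
`a = 6.08e-5`, `b = 0.09` — chosen once to give a life expectancy of about
75 years at birth (and 36 years at age 40), a plausible national level —
and treats the RR as configuration with a placeholder default of 2.0.
Because of this, the lifetime results are examined *directionally* and over
an RR grid of 1.5–3.0 rather than matched to the published point values;
`analysis/02_base_case.R` writes that grid.

### Numerical conventions

Rows of every transition matrix are built from the raw annual
probabilities; if a row's non-death outflow exceeds the mass left after
death the engine raises a misspecification error rather than renormalizing
silently. Because the raw-probability model stops being well-posed at
extreme ages (where `q·RR` approaches 1), propagation halts when the living
mass drops below an occupancy floor of `1e-5` (configurable); at that point
the remaining living mass contributes at most ~1e-4 of a life year, so the
truncation is numerically invisible while keeping every constructed matrix
valid across the supported RR range and across probabilistic draws.

Accrual uses end-of-cycle occupancy: the year between cycles `t−1` and `t`
is valued by the state occupied at cycle `t`, discounted by `(1+r)^{−t}`
with `r = 3%`/year for both costs and outcomes. This puts "first-year"
labels, cycle-1 remission and the first-year-only non-medical items on the
same cycle. The one-time surgery cost sits at cycle 0, undiscounted. A
half-cycle correction (averaging the two bounding occupancies) is available
behind a configuration switch and off by default. With this convention an
immediately-fatal toy cohort accrues zero life years.

## Costs, utilities and perspectives

The payer perspective counts direct medical costs; the societal perspective
adds direct non-medical costs (no productivity losses are included, because
none are among the inputs). All costs are 2023 baht, consumed as given —
currency-year adjustment and the cost-to-charge conversion are upstream of
this package.

Non-medical costs in the two pre-complication states are assembled from
per-visit items (travel, food, hotel, informal care at the visit) times
visit frequencies, annual items (informal daily care, hired assistance,
treatment outside the hospital — arm-specific for the non-remission state),
and first-year-only items (accommodation, home renovation) at cycle 1.
Complication states instead carry literature-derived annual totals. The
visit frequencies are **not published**: the defaults (4 outpatient
visits/year without remission, 2 with, 0.1 inpatient admissions/year) are
modelling assumptions chosen once so that per-state societal costs sit at
the order implied by the published lifetime cost gap between the two
perspectives; they are exposed in the run configuration.

The comparison reports dominance or the ICER; an ICER exactly at the
160,000 baht/QALY threshold counts as cost-effective (inclusive boundary).

## Uncertainty analysis

Probabilities and utilities carry beta distributions, costs gamma
distributions, each parameterised by method of moments from its mean and
SE, so the assigned distribution reproduces the published moments exactly.
One interview-derived cost has SE equal to its mean (informal care under
remission), which is simply a gamma with shape 1 and is accepted; zero-SE
parameters are treated as fixed rather than rejected.

One-way sensitivity re-runs the model at the 2.5th and 97.5th percentiles
of each parameter's distribution (the published tornado's ranges are not
stated, so the central 95% interval is this package's documented
convention), holding everything else at base means. The PSA draws all
parameters independently — no correlation structure is given — with one
master seed and a per-parameter substream keyed on the parameter name, so
adding a parameter never perturbs the draws of the others and runs are
reproducible bit-for-bit. The PSA point estimate is the ratio of mean
increments, matching how the published simulation summary is constructed,
and the acceptability curve is the fraction of draws with non-negative net
monetary benefit `λ·ΔQALY − Δcost` along a willingness-to-pay grid.

## Budget impact

The eligible population cascade starts from the 45.09 million Thais aged
18–65, takes the 6.36 million with BMI ≥ 30, interpolates obesity-class
shares (4.0 / 0.8 / 0.1% for classes I/II/III) linearly within the class
band containing the BMI 32.5 cut — giving 59.2% of the obese population —
and splits the result by the 11.1% T2DM share into a prevalent surgical
pool and an at-risk pool. Annual incident cases convert 8-year cumulative
incidences (22.52% men, 18.03% women) via `1 − (1−p)^{1/8}` and are held
constant over the horizon. The published headline counts (3,764,102;
417,865; 90,744) are carried as configuration constants because they embed
stratum-level rounding upstream; the cascade reports the re-derived values
alongside (e.g. 3,765,092 and ≈ 93,600 under the package's 50/50 sex-split
assumption, which is configuration because the per-sex pools are not
published).

The projection is undiscounted, the usual budget-impact convention (the
original does not state otherwise). By default the whole prevalent stock is
treated in year 1 and each incident cohort in its entry year; every treated
cohort then accrues the *expected* per-patient annual payer cost of its arm
by year since surgery, taken from the Markov trace so remission mix,
complications and deaths are reflected, with the one-time surgery cost in
the entry year. The uptake schedule is a configuration vector over the
prevalent stock and must sum to at most 1.

## The synthetic data generator

`generate_cohort()` simulates patient-level yearly histories with exactly
the transition structure above (entry at 40, uniform entry over a ten-year
window so observation is censored at 1–10 years), and
`estimate_transition_probs()` recovers annual probabilities as events per
person-year at risk, stratified the way the model consumes them. This
replaces the source hospital cohort, which cannot be redistributed, and the
person-year estimator replaces the original multivariate confounder
adjustment — synthetic data has no confounding by construction.

What passing tests show, and what they do not: parameter recovery at 5,000
patients per arm within three standard errors demonstrates that the
generator and the estimator agree on the model's own terms; it says nothing
about EHR realities such as informative censoring, measurement error in
remission status, or confounding by indication. One published descriptive —
19.1% of 2,109 non-surgical patients ever in remission — is *not*
reproducible from the published annual probability (0.0156/year compounds
to at most 14.6% over a ten-year window); the generator makes no attempt to
force it, and the surgical-arm fraction (63.3% of 30) is the one checked
within binomial error.

`generate_interview_sample()` draws cost/utility observations from the
assigned distributions, emulating the interview data behind the non-medical
cost and utility means, and `required_sample_size()` implements the
planning formula `n = ⌈z²σ²/(μ²ε²)⌉` whose worked case (z = 1.96,
σ = 0.5μ, ε = 0.15) gives 43 per group.

## Problem sizes and reproducibility

The default runs are the full study conditions: a lifetime horizon of up to
60 one-year cycles per arm, 1,000 PSA draws, a tornado over all 60
uncertain parameters, and synthetic cohorts of 30/2,109 (descriptives) and
5,000 per arm (recovery). Every stochastic stage takes an explicit seed;
the analysis drivers under `analysis/` record a manifest (input checksums,
seed, package version) next to their outputs.

## Known limitations

* The base-case point values depend on the synthetic life table, the
  placeholder mortality RR and the assumed visit frequencies, so they
  approximate but do not equal the published figures; orderings and
  threshold conclusions are the reproducible content.
* Only the first complication is modelled; second surgeries, revisional
  procedures and complications beyond the four included are out of scope.
* Parameters are sampled independently in the PSA; any real correlation
  (e.g. between year-indexed costs) is ignored.
* The budget projection keeps incident cases constant and ignores capacity
  constraints and payer-scheme composition.
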