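---
title: "Methods: comparing Parkinson's progression across research and real-world populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing Parkinson's progression across research and real-world populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pdprogression)
```

## The problem this package addresses

Parkinson's disease (PD) progression looks different depending on where you
measure it. Actively recruited research cohorts enroll younger patients,
assess them on structured visits with clinician-recorded rating scales, and
observe slow score change; passively collected real-world data (RWD) —
hospital EMRs and insurance claims — capture older patients, record rating
scales only incidentally in free-text notes, and show faster motor and
cognitive decline. Quantifying that divergence requires a chain of
non-trivial machinery: incident-cohort phenotyping from diagnosis codes,
extraction of rating scores from notes with an auditable error model,
rule-based clinical event detection, and survival/progression statistics
robust to irregular sampling.

The real data sources behind such comparisons are licensed and cannot ship
with an open package. `pdprogression` therefore pairs the full analysis
machinery with a *calibrated synthetic generator*: the generator's default
parameters are set to the published population values (ages at diagnosis,
score trajectories, event-time medians, recording sparsity), and the
package's acceptance surface is *parameter recovery* — the pipeline, run end
to end on synthetic cohorts, must give those values back. Passing this says
the machinery is faithful and unbiased under a known data-generating process;
it does not certify behavior under real-data pathologies the generator does
not model (see Limitations).

## The synthetic generator

Each source archetype (`research`, `research_survey`, `rwd_emr`,
`rwd_claims`) is a parameter block (`make_archetype_config()`); the key
calibrated defaults are:

| parameter | research | rwd_emr | rwd_claims | units |
|---|---|---|---|---|
| age at diagnosis (mean, SD 10, truncated 30–95) | 60.4 | 72.2 | 72.2 | years |
| fraction male | 0.67 | 0.578 | 0.567 | — |
| follow-up mean (capped at 12/15/12) | 6.2 | 3.8 | 3.1 | years |
| any recorded rating score | 0.912 | 0.081 | 0 | fraction |
| UPDRS total: intercept, slope | 28.25, 1.54 | 18.93, 3.87 | — | points, points/yr |
| MMSE: intercept, slope | 28.7, −0.11 | 25.8, −0.28 | — | points, points/yr |
| median time to H&Y ≥ 3 | 18 (unreached) | 5.6 | 5.6 | years |
| therapy-initiation delay mean | 1.0 | 3.3 | 3.3 | years |

Model choices, with the reasoning where the design was open:

- **Ages** are truncated normal on [30, 95] with SD 10 (matching published
  interquartile ranges); the location is solved numerically so the
  *truncated* mean equals the configured mean exactly.
- **Follow-up** is exponential, truncated at a records-era cap (12 y for the
  research cohort — clinical scores in these settings are effectively
  available only for about the first decade — 15 y EMR, 12 y claims), with
  the rate solved so the truncated mean equals the configured mean. Without
  the cap, the exponential tail produces a handful of patients with 40+
  observation years whose leverage dominates pooled regressions.
- **Encounters** are a homogeneous Poisson process (2/yr research, 4/yr EMR,
  5/yr claims) over the whole history window; research archetypes add annual
  structured study visits at which scores are always recorded for recording
  patients.
- **Score trajectories** are linear per patient: population intercept plus a
  patient random intercept (SD 3 UPDRS, 0.4 MMSE), observation noise (SD 2
  UPDRS, 0.6 MMSE, 0 H&Y), clamped to the scale range. H&Y is
  floor-quantized to half stages, so the quantized stage reaches 3 exactly
  when the latent line does; its per-patient slope is set so the crossing
  happens at the drawn event time. MMSE noise is kept small deliberately:
  with an intercept of 28.7 on a 0–30 scale, large noise interacts with the
  ceiling and biases the recovered intercept downward.
- **Event times** (H&Y ≥ 3, cognitive decline) are Weibull with shape 1.5 (a
  mildly increasing hazard) and scale solved from the configured median —
  the published evidence pins medians only. The research H&Y ≥ 3 median (18
  y) is set so the survival median is not reached within follow-up, matching
  the "> 10 years" character of research-cohort reporting.
- **The cognitive-decline proxy event** is comonotone-coupled to the latent
  MMSE trajectory: event times keep their Weibull marginal but are
  rank-matched to each patient's MMSE ≤ 25 crossing time, so the
  utilization-based and score-based definitions agree positively, as they
  must for the phi-coefficient validation to be meaningful.
- **Therapy initiation** delays are truncated normal (SD 0.5); the start
  materializes as a fill sequence (30 d + 30 d at day 40 + 40 d at day 110,
  then maintenance fills) that satisfies the initiation episode rule
  whenever the whole sequence fits inside follow-up, with the first fill
  linked to a PD-coded encounter. Real-world initiation is 2.3 years later
  than research initiation by construction.
- **Score recording** is per-patient Bernoulli whose log-odds carry a weak
  "specialist visit" signal (odds ratio 1.5 on 30% of patients), with the
  base rate solved so the marginal recording probability equals the
  configured value. This gives the missingness audit a realistic
  weak-signal target (AUC ≈ 0.55–0.6) rather than pure chance.
- **Year-resolution diagnosis dates** (research archetypes): the recorded
  diagnosis date is January 1 of the diagnosis year. Sex effects on
  trajectories default to 0 but are exposed as config knobs.
- **Coverage intervals** (claims) run from history start to censoring, with
  a geometric gap (30–120 d) inserted with probability 0.1 to exercise the
  coverage-based quiescence variant.

Notes render scores through fixed template phrases ("Hoehn and Yahr stage:
X.", "UPDRS total: X.", "MMSE: X/30.") interleaved with numeric distractor
sentences; the generator records exactly what it rendered as note-level
ground truth. An ambiguous variant renders two conflicting values to
exercise consensus flagging.

## Cohort phenotyping

Incident PD is phenotyped in a fixed order: first observed PD diagnosis
(ICD-9 332 prefix / ICD-10 G20, dot-insensitive), then the 730-day
quiescence rule, then a confirmatory PD code, then parkinsonism-mimic
exclusions, with per-stage attrition counts. Boundary semantics follow the
inclusive "at least" reading and are pinned by tests: an encounter exactly
730 days before diagnosis passes quiescence; a confirmatory code exactly 30
days after passes. The quiescence rule is encounter-based (EMR), requiring
one encounter at or before diagnosis minus the window, or coverage-based
(claims), requiring merged coverage intervals (gap tolerance configurable,
default 0) to contain the whole window. Research archetypes bypass
quiescence and exclusions — their participants enter with an explicit,
screened diagnosis date.

## Score extraction and the consensus protocol

Extraction is backend-pluggable: a backend maps (note text, scale, exemplar
polarity, run index) to a value token. The package ships a deterministic
reference backend that parses the synthetic templates (with an "ambiguous"
sentinel when a scale appears with conflicting values) and a noisy mock that
corrupts each run independently with probability *p* — the protocol's error
model is tested against the closed-form binomial flag rate. A real LLM can
be slotted in by implementing the same contract; nothing in the package
requires one.

Each note/scale runs 10 positive-exemplar and 10 negative-exemplar
inferences. The consistency rule is applied *per polarity set*: the modal
output must occur at least 9 of 10 times in each set, with no modal tie, and
the two modal outputs must agree; otherwise the note is flagged and its
value withheld pending manual correction. The per-set reading (rather than a
pooled 18-of-20) matches the reported failure signature of notes agreeing
only 4/10 and 5/10 across the two sets; the pooled variant is available
behind `pooling = "pooled"`. Modal ties flag the note — a tie is itself
inconsistency. Output tokens are normalized before voting (decimal commas,
Roman numerals I–V, "/30" denominators, trailing zeros). Corrections may
only overwrite flagged notes; consensus-accepted values are never silently
replaced. Stratified audit samples (gold-positive / model-positive /
model-negative / gold-negative) support the accuracy computation, with
none-equals-none counted correct.

## Clinical events

- **Therapy initiation** (any PD therapeutic, or levodopa alone): the
  earliest first fill such that the fill is linked to a PD-coded encounter
  (or a same-day PD encounter when no link is recorded), cumulative days
  supply within 180 days exceeds 90, and a further fill falls more than 90
  but at most 180 days after the first. A single 90-day fill never
  qualifies. Whether the "> 90 days of pills" accumulates within the window
  or over the whole sequence is ambiguous; the windowed reading is
  implemented.
- **Cognitive decline, RWD proxy**: (first MCI code AND first
  cognitive-medication fill at a PD-coded encounter — dated at the later of
  the pair) OR a cognitive neurology referral; the and/or grouping is the
  conservative reading, with an "any-of-three" variant behind a flag.
  The score-based definition is the first MMSE ≤ 25 (inclusive).
- **H&Y threshold**: first recorded stage ≥ 3. Detected times are the first
  *observation* at or after the true crossing — on synthetic data with zero
  H&Y noise this is asserted exactly.
- **Adverse events** (falls/fractures, depression): the event code as
  primary or admitting code of an encounter with an inpatient stay or
  recorded treatment; any event code during the pre-diagnosis quiescence
  window voids eligibility for that event's analysis.
- **Phi validation**: the agreement between the MMSE and utilization
  definitions is the phi coefficient of the 2×2 table, computed at visit
  level (patient-level variant provided); constant vectors are an error, not
  a zero.

Censoring is the last encounter (EMR/research) or coverage end (claims).

## Statistics

- **Kaplan–Meier** curves come from the survival package (product-limit,
  Greenwood/log confidence bands); the median is the smallest time with
  S(t) ≤ 0.5, reported as "not reached (> horizon)" when the curve never
  gets there. Tests pin the estimator to a brute-force product-limit oracle
  on small inputs, and the log-rank test to a permutation null.
- **Group differences** route by the standard applied recipe: Shapiro–Wilk
  on both samples (α = 0.05), then Levene (median-centred) choosing Welch
  versus pooled t; non-normality routes to Mann–Whitney U. The route is a
  pure function of the three sub-test p-values.
- **Progression models** are per-visit OLS of score on years since
  diagnosis, age at diagnosis and sex (education optional where collected),
  reporting the annual slope and the intercept at diagnosis evaluated at the
  sample's covariate means. Repeated visits per patient violate
  independence, so patient-cluster-robust (sandwich) standard errors are the
  default inferential SEs; rank deficiency is a hard error naming the
  collinear covariates, residual normality is checked by Shapiro–Wilk, and
  variance inflation factors are reported with a flag at VIF ≥ 10. No
  multiple-testing correction is applied; p-values are reported raw and the
  report says so.
- **Year-resolution diagnosis dates** enter analyses with a mid-year (July
  1) time origin, which is mean-unbiased when diagnoses are uniform within
  the year; the residual uniform origin error (variance 1/12 y²) is handled
  by regression calibration — the slope is divided by the reliability ratio
  1 − (1/12)/Var(t | covariates) and the intercept recentred through the
  sample means. Times since diagnosis may be slightly negative under this
  convention; truncating them at zero would bias the fit and is deliberately
  not done.
- **Slope comparisons** between sources use a pooled model with a
  source-by-time interaction (Wald test, cluster-robust); the difference of
  separate per-source fits is reported alongside and coincides with the
  interaction estimate in balanced designs.
- **The missingness audit** asks whether per-patient features predict score
  presence: a logistic classifier under 5-fold cross-validation, reporting
  pooled out-of-fold AUC.

## Problem sizes, seeds and determinism

Everything is seeded. `run_pipeline()` derives one seed per stage from the
master seed via a stable string hash, so runs are reproducible end to end
and stages are independently replayable. The test suite works at n =
150–2000 patients per archetype; the calibration-recovery checks use n =
2000 (research) to 5000 (EMR, whose 8.1% score-recording rate needs the
larger base) — at those sizes each recovered quantity's 2-standard-error
band is a few percent of its value. The acceptance script regenerates
everything from scratch at the same sizes from a single command-line seed.

## Known limitations

- Linear trajectories with a patient random intercept only: no slope
  heterogeneity, no floor/ceiling dynamics beyond clamping, no
  practice/on-off effects. Recovery tests therefore certify unbiasedness of
  the machinery, not robustness to trajectory misspecification.
- Censoring is independent of progression; real-world loss to follow-up is
  plausibly informative.
- The note generator's language is templated; the reference extractor is a
  parser, not a language model. The consensus protocol's statistical
  behavior (flag rates, audit properties) transfers; extraction *accuracy*
  on real notes does not.
- Comorbidity structure, mortality, costs and genetics are not modeled; the
  mimic-exclusion and adverse-event vocabularies are synthetic stand-ins.
- The claims archetype's coverage-gap process is geometric and single-gap;
  real enrollment churn is lumpier.
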