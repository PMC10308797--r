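---
title: "Simulating drug development process segments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating drug development process segments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpsim)
```

## The problem

An oncology drug development process (DDP) is a sequence of trials — phase I
dose finding, phase II screening, phase III confirmation — in which each
trial's result gates and shapes the next. Designing an early trial only for
its own operating characteristics ignores its downstream consequences: a
phase II trial with respectable stand-alone power can still leave the
two-trial *segment* with a much lower probability of overall success,
because the effect estimate it passes forward is noisy and conditioned on
rejection, hence biased upward.

`ddpsim` models DDP segments of exactly two consecutive trials with a
go/no-go gate. Everything is driven by a binary endpoint, the objective
response rate (ORR), with `ORR1` for the experimental treatment and `ORR0`
for the standard of care. The package's job is to estimate, by seeded
Monte-Carlo replication, segment-level performance metrics:

* **DDP power** — the probability that the first trial is positive *and*
  the triggered second trial is positive, under a stated truth scenario;
* **expected total enrollment** across both trials;
* **probability that an enrolled patient receives an unsafe or ineffective
  dose** (segment B);
* **expected duration** in months under a linear accrual model.

## Segment A: phase II single arm, then phase III RCT

The phase II trial enrolls `n2` patients and tests `H0: ORR1 <= ORR0`
(historical `ORR0 = 0.4`) with a one-sided exact binomial test at level
`alpha = 0.05`. The rejection rule is the standard exact convention: reject
when the response count reaches the smallest `r` with
`P(X >= r | Binomial(n2, ORR0)) <= alpha`, ties at exactly `alpha`
rejecting. Tail probabilities come from `pbinom`, which is numerically
stable at any `n` used here.

On rejection, a 1:1 phase III RCT is sized from the phase II point estimate
`ORR1-hat` against the historical 0.4: the smallest per-arm `n` whose
**exact unconditional power** of the one-sided Fisher exact test reaches
`target_power = 0.90`, subject to a hard cap of 400 patients total. Exact
unconditional power sums the joint `Binomial(n, p1) x Binomial(n, p0)` mass
over all outcome tables whose hypergeometric-tail p-value is at most
`alpha`. When even the capped trial misses the target, the phase III still
runs at 400 — the cap limits trial size, not the decision to proceed.

Two numerical points matter. First, exact-test power is a *sawtooth* in
`n`: adding a patient can shift the critical region and lower power by up
to several percentage points at small `n` (our test suite verifies drops up
to ~5 points with a strictly increasing trend over 10-patient steps). The
sample-size search therefore scans linearly from `n = 2` rather than
bisecting. Second, the Fisher rejection region depends only on `(n, alpha)`,
so it is cached as a matrix per size; a power evaluation is then a bilinear
form in two binomial pmf vectors, and the full linear scan costs
milliseconds. Sizing results are additionally memoized per estimate, since
`ORR1-hat` takes at most `n2 + 1` distinct values in a run.

**Sizing convention.** Whether "sample size for 90% Fisher-test power"
means exact unconditional power, a normal approximation, or a two-sided
variant is a genuinely open design choice, and it moves expected phase III
enrollment by tens of percent. The package's default is exact unconditional
power for a one-sided test, matching the one-sided null; the two-proportion
normal approximation is available as `rct_design(sizing = "normal")` for
sensitivity analyses. The one-sided choice follows from the tested
hypothesis; a two-sided 0.05 test would contradict it.

## Segment B: phase I CRM, then phase II single arm

The phase I trial is a one-parameter Bayesian Continual Reassessment Method
(CRM) with the empiric power model: dose `j` has toxicity probability
`skeleton_j^exp(beta)` with prior `beta ~ Normal(0, 1.34^2)` — the
conventional empiric-model default. Patients enter one at a time from
`start_dose`; after each binary dose-limiting-toxicity (DLT) outcome the
posterior mean toxicity per dose is recomputed and the next patient gets
the dose whose estimate is closest to the target `p = 0.25` (a common
oncology threshold), with ties toward the lower dose and, by default, no
skipping of untried levels upward. At the end, the **MTD** is the highest
dose with estimated toxicity at or below `p`; if even dose 1 exceeds it, no
dose is selected and the DDP stops — a post-trial safety gate, not a
mid-trial stopping rule.

Defaults that the data cannot identify are explicit, package-chosen values:
the six-level skeleton `(0.05, 0.12, 0.25, 0.40, 0.55, 0.68)` centers the
prior MTD on level 3, `start_dose = 3`, one patient per cohort. All are
overridable through `crm_design()` and the config schema.

**Quadrature.** The posterior mean `E[skeleton_j^exp(beta) | data]` is a
one-dimensional integral. We evaluate it by composite Simpson on a fixed
2401-node grid over `beta` in `[-12, 12]`: with a prior sd of 1.34 the
integrand's mass lies far inside that range (the prior density at the
endpoints is below 1e-17, and a bounded binary-data likelihood cannot move
mass outside it), the rule is deterministic, and precomputing the per-dose
curves on the grid makes a model refit a handful of vectorized operations —
which is what makes simulating thousands of CRM trials cheap. The test
suite checks agreement with an independent 100,000-point trapezoid
integration to 1e-6 on random datasets, far tighter than any decision
boundary in the design.

The selected dose `j*` feeds a fixed 42-patient single-arm phase II trial
(42 being the smallest size with 80% exact binomial power for 0.4 vs 0.6 at
one-sided 0.05 — `minimum_sample_size(0.4, 0.6, 0.05, 0.8, 10, 200)`), with
responses and toxicities drawn at dose `j*`'s true rates. The trial is
positive when the efficacy test rejects *and* the observed toxicity rate is
at most `tox_monitor_threshold` (default 0.25, mirroring the phase I
target). The segment is counted positive only when, additionally, `j*` is
*truly* safe and effective (true DLT probability at most `p`, true ORR
above 0.4); the variant without the toxicity monitor is reported alongside
as `ddp_power_no_monitor`, since the gate's role in segment positivity is a
design choice. The exposure metric is the mean over replicates of the
within-replicate fraction of patients treated at unsafe or ineffective
doses — the probability that a randomly chosen enrolled patient in a
randomly chosen program realization is so treated — not a ratio of
expectations.

For settings with non-monotone dose–response, `select_optimal_dose()`
implements the optimal-dose (OD) rule — highest estimated ORR among doses
with acceptable toxicity — and `make_nonmonotone_dose_scenario()` provides
a truth where OD and MTD selection disagree. The full adaptive OD trial
design is out of scope.

## Segment C: adaptive enrichment phase II, then phase III RCT

The phase II trial randomizes over a continuous biomarker `x ~ Uniform[0,1]`
with nine candidate eligibility cutoffs `0.1, ..., 0.9`. Accrual comes in
three stages (50%, 25%, 25% of `n2`, rounded; stage 3 absorbs the
remainder) with an interim analysis after each of the first two. Patients
are randomized 1:1 within consecutive enrollment pairs — the minimal
structure that creates the pairs a McNemar analysis needs; an odd stage
leaves one unpaired patient who counts toward enrollment but contributes no
paired information.

**Interim rule.** The enrichment literature defines a design family, not a
unique algorithm, so the package implements one simple, monotone member:
among candidate cutoffs at or above the current one with at least
`min_subgroup_pairs = 5` complete pairs above them (both members), move to
the cutoff maximizing the estimated ORR difference in the above-cutoff
subgroup; ties break toward the lower cutoff (the larger population); keep
the current cutoff when nothing qualifies or nothing strictly improves.
Eligibility therefore never loosens. The final analysis applies the exact
one-sided McNemar (sign) test, `P(X >= b | Binomial(b + c, 1/2))` over the
discordant pairs among all complete pairs meeting the final cutoff; the
exact form is chosen over the asymptotic one for small-subgroup validity.
No further multiplicity adjustment is made for the interim adaptation: the
adaptation touches eligibility, not the test's pairing, and the null
simulations in the test suite confirm the segment-level false-positive rate
stays within bounds.

A positive phase II triggers a phase III RCT sized (same exact Fisher
machinery and 400-patient cap as segment A) from the *subgroup* estimates
the enrichment trial reports — rejection guarantees the experimental
estimate exceeds the control one — and enrolling biomarkers uniformly from
`[final cutoff, 1)` with responses from the true curves.

## Truth scenarios

The scenario generators define the study conditions; their defaults are
fixed, documented choices, not tuning knobs.

* `make_example1_scenario()`: `ORR1 = 0.6`, `ORR0 = 0.4` (the segment A/B
  effect size); `null = TRUE` sets both to 0.4 for error-rate studies.
* `make_default_dose_scenario()`: six doses with strictly increasing
  toxicity `(0.02, 0.06, 0.12, 0.20, 0.35, 0.50)` and non-decreasing ORR
  `(0.15, 0.30, 0.50, 0.60, 0.65, 0.67)`, built so that *exactly* doses 3
  and 4 are safe (toxicity ≤ 0.25) and effective (ORR > 0.4). The
  qualitative constraints are the scenario's substance; the specific
  probabilities are package fixture values.
* `make_default_biomarker_scenario()`: logistic experimental curve crossing
  the flat `ORR0 = 0.4` exactly at `x = 0.6` (slope 5 on the logit scale, a
  fixture value): patients above 0.6 benefit, patients below do better on
  the standard of care.
* `enrollment_model()`: 4 patients/month in the first trial, 10 in the
  second, 6-month gap and 6-month follow-ups — plausible oncology
  defaults, fully overridable; durations are linear in patients enrolled.

What these scenarios deliberately do **not** emulate: patient dropout,
accrual ramp-up or seasonality, non-uniform biomarker distributions,
response misclassification, correlation between toxicity and response
within patients, and drift between phase II and phase III populations
beyond the explicit biomarker enrichment. Passing tests therefore
demonstrate the internal coherence of the designs under clean binomial
sampling, not robustness to those real-data features.

## The replication engine

Replicate `i` of a run with base seed `s` runs under its own RNG seed
`rep_seed(s, i)` (a Lehmer-style map into `[1, 2^31 - 2]`). Consequences,
both verified in the suite: identical `(segment, n_reps, seed)` give
bit-identical metrics tables, and splitting a run into consecutive blocks
(`first_rep`) and pooling reproduces the full run exactly, independent of
execution order. Proportions carry the exact Monte-Carlo standard error
`sqrt(p(1-p)/n_reps)`; means carry `sd/sqrt(n_reps)`; single-replicate runs
report `NA` standard errors. Selection distributions (dose levels or
cutoffs, plus `none` for a negative first trial) are exact replicate
frequencies and sum to one.

## Problem sizes and verification

The test suite favors exhaustive enumeration where feasible: binomial
critical values and powers are checked against direct pmf summation;
Fisher p-values against conditional table enumeration and, independently,
`fisher.test`; McNemar against `binom.test`; the CRM posterior against
dense-grid integration. Segment A's simulated DDP power and enrollment are
cross-checked against a semi-analytic decomposition — binomial mass over
phase II outcomes times exact phase III power at the data-driven size —
which requires no phase III simulation at all.

Monte-Carlo checks use 10,000 replicates for the headline segment-A
quantities and the null false-positive bounds, and 100–4,000 replicates for
properties that are either cheap to establish (gating invariants,
determinism) or expensive per replicate (CRM and enrichment trajectories);
each stochastic assertion carries a 3-standard-error tolerance.

## Known limitations

* Segments contain exactly two trials; longer chains are out of scope.
* Phase III sizing uses the point estimate only, not its confidence
  interval — the published convention for the sizing calculation is not
  fully specified, and the `sizing = "normal"` switch brackets the
  plausible range.
* The phase II single-arm designs analyze once, at the end (no Simon
  two-stage, no interim futility).
* The exact binomial test is conservative at small `n`; designs quoted as
  "80% power" under looser conventions can fall short under the exact
  rule (at `n = 20` for 0.4 vs 0.6 the exact power is 41.6%).
* The enrichment interim rule is one member of a design family; other
  members shift the cutoff-selection distribution.
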