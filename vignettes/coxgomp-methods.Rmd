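---
title: "Methods: Gompertz survival modelling and score-test GWAS for healthspan"
author: "coxgomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gompertz survival modelling and score-test GWAS for healthspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxgomp)
```

## The phenotype

Healthspan is defined as the age at the first of a fixed list of
age-associated chronic diseases, or death.  Diagnosis histories arrive
from several sources of unequal reliability: in-patient hospital
records (ICD-10 coded), cancer and death registries, and self-reported
diagnoses from a verbal interview.  `condition_onsets()` resolves them
with a source-priority rule: for each participant and condition the
onset is the *minimum age over hospital and registry records*; the
interview minimum is used only when no hospital/registry record exists
for that pair.  The rule reflects the asymmetry of the sources — an
absent hospital record cannot be distinguished from an absent disease,
so self-report fills gaps but never overrides clinical data, even when
it reports an earlier age.

`healthspan()` then takes the minimum onset over the selected
conditions; `delta = 1` iff that minimum exists and does not exceed the
follow-up end `t2`.  Pre-enrollment diagnoses (age < enrollment age
`t1`) are accepted as events, because the full clinical history is
considered known at recruitment.  Two deliberate choices where the
problem is under-determined:

* **Tie-break.**  When two conditions share the minimal onset age the
  terminating condition is the first in the user-supplied condition
  order.  Any fixed order works; determinism is what matters.
* **Censoring ages.**  `t2` for event-free participants must be
  supplied (in the synthetic cohort, `t1 + followup_years`).  It is a
  required input rather than something inferred from the data, because
  registry extracts typically do not record it per participant.

The `death_mode = "censor"` variant removes death from the event set
and lets a death age that precedes every other onset truncate `t2`
instead — the standard sensitivity analysis for whether treating death
as an event distorts the genetic signal.

ICD-10 codes can be matched exactly or by prefix (`"C"` matches the
whole cancer block); both behaviours are exposed because code lists in
the wild mix block prefixes and full codes.

## Age-specific incidence

The incidence rate in the age window `[t, t + dt)` is
`m = N_d / (dt · N_h)`, where the risk set contains participants who
are event-free at `t` and whose diagnosis status is observable over the
whole window (`t + dt < t2`), and `N_d` counts risk-set members with
`t <= td < t + dt`.  All comparisons are half-open and strict exactly
as written, so integer-rounded ages fall into exactly one window of a
unit grid — this is the property the conventions buy, and it is tested
as such.  An empty risk set yields an explicit `NA`, never a zero rate.

The enrollment-restricted risk set additionally requires `t1 < t`.  It
matters only when the event prevents later enrollment — death being the
canonical case — and is always a subset of the standard risk set.

Confidence intervals default to the exact Poisson interval on `N_d`
with exposure `N_h · dt`, the standard choice for rare-event incidence;
a normal approximation is available for large counts.
`incidence_slope()` fits weighted least squares of log-rate on age over
windows with at least 5 events (weights = event counts), recovering the
Gompertz shape and the doubling time `ln 2 / slope`.

## Maximum-likelihood fitting

The negative log-likelihood integrates the hazard from age 0, with no
delayed-entry term for enrollment at `t1`.  That is a modelling
commitment, not an oversight: the phenotype includes pre-enrollment
history, so participants are not conditioned on being event-free at
enrollment.  A left-truncated variant
(`left_truncated = TRUE`) that subtracts each participant's cumulative
hazard at `t1` is provided for sensitivity analysis only.

Numerics:

* Optimization runs in `(log h0, log Γ, β)` — unconstrained coordinates
  for the two positive parameters — with the analytic gradient, under
  BFGS at `reltol = 1e-12`.
* **Initialization.**  `Γ0 = 0.1`/yr (the scale of adult morbidity
  acceleration) and `h0` at its *profile maximum given* `Γ0`, i.e. the
  closed-form solution of the baseline score equation at `β = 0`.
  Starting on the score surface matters: the log-Γ gradient vanishes as
  `Γ → 0`, so a mismatched `(h0, Γ0)` pair can send a line-search
  optimizer down that flat ridge into the exponential sub-model, a
  stationary region it cannot leave.
* **Polish.**  BFGS stops when the objective stops moving, which can
  leave the gradient above tolerance; up to ten full Newton steps from
  the observed Hessian then drive the sup-norm of the gradient below
  `1e-6 · N_d`.  Convergence is declared only when both the optimizer
  reports success and that gradient bound holds; anything else is
  flagged on the returned object, never silent.
* Standard errors come from the inverse observed information in the
  optimization coordinates, mapped to the natural scale by the delta
  method.

At the optimum the baseline score equation `Σ_n H_n = N_d` holds (the
fitted cumulative hazards sum to the event count); tests assert it to
relative `1e-6`, and it is what makes the GWAS weights below exact.

Derived summaries: mean span `(ln(Γ/h0e^{βx}) − γ_E)/Γ` with the
Euler–Mascheroni constant `γ_E ≈ 0.5772` (asymptotically valid for
`Γ/h0 ≫ 1`; a warning fires below ratio 100, where it degrades
against numerical integration of the survival curve); the span shift
`Δβ/Γ` for a covariate contrast; and the doubling time `ln 2 / Γ`.  At
a male–female log-hazard ratio of 0.26 and shape 0.098/yr the closed
form gives a 2.65-year span difference — reported as is.

## The perturbative score test

Jointly estimating a variant's effect on `h0` and on `Γ` is ill-posed
for small effects, so `Γ` is held fixed at its null-fit value and the
per-variant effect is the first-order expansion around the null model.
The weights `ρ_n` are each participant's share of the fitted cumulative
hazard; the residuals `δ_n − N_d ρ_n` are martingale residuals of the
fitted model and sum to zero by the score equation.

The notation `⟨δs²⟩_ρ` is implemented as the ρ-weighted *central*
variance of the dosage, `Σ ρ_n (s_n − ⟨s⟩_ρ)²`.  This is the unique
interpretation under which the translation invariance of the
numerator (guaranteed by zero-sum residuals) carries over to the full
statistic, and it is validated empirically: across null replicates the
closed-form `σ_s` matches the Monte-Carlo standard deviation of
`β_s` within 10%, and the type-I error at `α = 0.05` is nominal.

Conventions: missing dosages are mean-imputed per variant (the standard
dosage-GWAS convention); p-values are two-sided normal on
`z = β_s/σ_s`; QC uses strict inequalities — effective minor allele
count `2·MAF·N·info > 200` and `info > 0.7` — so boundary values fail.
Flipping the coded allele (`s → 2 − s`) flips the sign of `β_s` and
leaves `|z|` unchanged.

Genomic control uses the median estimator
`λ = median(χ²)/qchisq(0.5, 1)`; adjustment divides χ² by λ, recomputes
p, keeps `β` and inflates `se` by `√λ` so the triple stays consistent.
By default λ < 1 is warned about and not applied.

## Replication and power

Stratified replication combines per-stratum statistics by
inverse-variance fixed effects — the standard for GWAS replication
across ancestry strata, and consistent with reporting a single
replication effect per variant.  The replication threshold is
Bonferroni `α/m` computed exactly (the χ²₁ upper quantile at
`0.05/12` is 8.21, printed as 8.2 elsewhere; it is computed, never
hard-coded).  Replication power models the replication statistic as
non-central χ²₁ with
`NCP = (T²_disc − 1)·N_rep/N_disc`,
`T²_disc = (β/se)²/λ_LDSC`.  The formula goes negative for sub-null
signals, where the NCP is floored at 0 — power then equals α, the
correct null-continuity limit.

## The synthetic cohort

The generator draws event ages by the exact inverse CDF of the Gompertz
proportional-hazards model: `t = ln(1 + ΓE/(h0 e^η))/Γ` with `E`
standard exponential, so the cumulative hazard evaluated at sampled
ages is standard exponential (tested by probability-integral
transform).  Around it, the cohort design mirrors a mid-life biobank:
enrollment ages uniform on [40, 70) years (configurable — the true
enrollment distribution of any real cohort is not uniform, and nothing
downstream assumes it), 8 years of administrative follow-up,
pre-enrollment history retained, an interview-only recording
probability for non-registry diagnoses, and an optional integer
rounding of ages to exercise the half-open window conventions.

Genotypes are Hardy–Weinberg binomial(2, MAF) hard calls; imputation
noise mixes the hard call with its population mean `2·MAF` with weight
`√info`, which reproduces the variance-ratio info statistic used by
imputation tools at the target value.  Multi-condition histories use
independent per-condition Gompertz clocks — the minimal assumption
consistent with modelling only the first event; it makes tallies and
per-condition screens testable but deliberately omits comorbidity
correlation.  Also absent, by design: linkage disequilibrium between
variants, relatedness, and population stratification.  Passing tests
therefore demonstrate correctness of the estimators under the model's
own assumptions, not robustness to the confounders of real cohort
data.

A single seed threads through all draws; equal seeds give
byte-identical cohorts.

## Problem sizes and runtime

The test suite simulates cohorts of 10³–10⁵ participants: parameter
recovery runs at n = 10⁵ (shape recovered within ±0.005 of truth),
the perturbative-vs-joint-ML comparison at n = 2×10⁴ over 50 variants
spanning per-allele effects in [−0.1, 0.1], and null calibration at
n = 5×10³ with 500 variants.  The full suite completes in well under a
minute on one CPU; the vectorized likelihood makes a 10⁵-participant
fit take about a second.

One caveat surfaced by the calibration study: the genomic-control
median estimator over only 500 independent variants has a sampling
standard deviation of about 0.10, so a single 500-variant λ is a noisy
calibration check even for a perfectly calibrated statistic (the mean
χ² over thousands of null statistics sits at 1.00).  λ should be read
on screens of many thousands of variants.

## Known limitations

* The default likelihood has no delayed-entry term (see above); with
  strong event-driven selection into the cohort the left-truncated
  variant should be compared.
* The score test is first-order: for per-allele effects well beyond
  |0.1| on the log-hazard scale its estimates compress towards zero
  relative to the joint ML refit (tested agreement: 5% relative / 0.01
  absolute within that range).
* No X-chromosome dosage model, no relatedness correction, no LD-aware
  post-processing (clumping, conditional analysis).
* `α/m` is computed exactly; printed roundings of such thresholds in
  the literature occasionally disagree with their own arithmetic, and
  no attempt is made to reproduce inconsistent roundings.
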