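# coxgomp

Survival modelling and genome-wide association testing for
*healthspan*-type phenotypes: the age at the first of a fixed set of
chronic diseases (or death), treated as a time-to-event trait in a
mid-life biobank cohort.

`coxgomp` is aimed at statistical geneticists and epidemiologists who
want to

* harmonize multi-source diagnosis histories (hospital ICD-10 records,
  self-reported interview codes, cancer/death registries) into
  per-condition first-onset ages and a disease-free-survival phenotype;
* estimate non-parametric age-specific incidence rates with careful
  half-open risk-set conventions that tolerate integer-rounded ages;
* fit a Gompertz proportional-hazards model by maximum likelihood; and
* screen millions of genetic variants against the fitted model with a
  closed-form score statistic, orders of magnitude faster than
  re-fitting the survival model per variant.

## The model

The hazard of the first morbidity at age *t* for an individual with
covariates *x* is

```
h(t, x) = h0 · exp(Γ t + β·x)
```

with baseline hazard `h0` (per year), Gompertz shape `Γ` (per year; risk
doubling time `ln 2 / Γ`), and log-hazard-ratio coefficients `β`.  With
event/censoring ages `T_n = min(td_n, t2_n)` and event indicators
`δ_n`, the negative log-likelihood is

```
L = Σ_n (h0 e^{β·x_n} / Γ)(e^{Γ T_n} − 1) − δ_n (log h0 + β·x_n + Γ T_n)
```

minimized over `(log h0, log Γ, β)` with an analytic gradient.

Per-variant effects use a perturbative expansion around the fitted null
model.  With weights

```
ρ_n = e^{β·x_n}(e^{Γ T_n} − 1) / Σ_m e^{β·x_m}(e^{Γ T_m} − 1)
```

(normalized so `Σ ρ_n = 1`, and equal to each individual's share of the
fitted cumulative hazard at the MLE), the per-allele log-hazard-ratio
estimate for a dosage vector `s` and its standard error are

```
β_s = Σ_n s_n (δ_n − N_d ρ_n) / (N_d ⟨δs²⟩_ρ),   σ_s² = 1 / (N_d ⟨δs²⟩_ρ)
```

where `N_d = Σ δ_n` is the event count and `⟨δs²⟩_ρ` is the ρ-weighted
variance of `s`.  The numerator is a covariance of dosages with
martingale-type residuals `δ_n − N_d ρ_n`; statistical power is driven
by the number of diagnosed individuals, not the cohort size.

Supporting machinery: strict-inequality variant QC (effective minor
allele count `2·MAF·N·info > 200`, imputation `info > 0.7`),
genomic-control adjustment from the median χ² estimator,
inverse-variance fixed-effect meta-analysis, and replication power via
the non-central χ² with `NCP = (T²_disc − 1)·N_rep/N_disc`.

A synthetic-cohort generator produces diagnosis records, covariates and
Hardy–Weinberg dosage panels from exactly this generative model, so the
whole pipeline is testable without access to any real cohort.

## Worked example

```r
library(coxgomp)

spec <- simulation_spec(
  n_participants = 20000, seed = 42,
  conditions = data.frame(name = "morbidity", h0 = 1e-4, gamma = 0.098),
  covariate_effects = c(sex = 0.26),
  enrollment_range = c(40, 70), followup_years = 8)
coh <- simulate_cohort(spec)

onsets <- condition_onsets(coh$diagnoses, coh$condition_map)
hs     <- healthspan(onsets, coh$followup)
fit    <- coxgomp_fit(hs, build_design(coh$covariates))
print(fit)
#> Gompertz proportional-hazards fit
#>   n = 20000, events = 9389, -logLik = 44338.6998, converged: TRUE
#>   h0 = 0.0001058 /yr, gamma = 0.0972 /yr (doubling time 7.13 y)
#>   coefficients (log hazard ratio):
#>  term estimate      se     z         p
#>   sex   0.2663 0.02071 12.86 7.713e-38
```

The generating values (`gamma` 0.098/yr, male log-hazard ratio 0.26)
are recovered within sampling error; the fitted shape corresponds to a
risk doubling time of about 7 years, and the sex effect to a mean
healthspan difference of `span_shift(0.266, 0.097) ≈ 2.7` years.
Variant screening then runs off the fitted null model:

```r
w   <- residual_weights(fit, hs, build_design(coh$covariates))
out <- run_gwas(panel, w)          # panel from read_dosages() or the simulator
lam <- genomic_control_lambda(out$z^2)
```

A command-line pipeline (`simulate`, `build-phenotype`, `incidence`,
`fit`, `gwas`, `meta`, `power`) is installed at
`system.file("cli", "coxgomp-cli.R", package = "coxgomp")`.

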