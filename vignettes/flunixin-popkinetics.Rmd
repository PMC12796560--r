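---
title: "Population disposition of flunixin in horses: model, estimation and regulatory detection times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population disposition of flunixin in horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`popkdt` models the disposition of flunixin after intravenous bolus
dosing in horses, and everything downstream of it that matters for
medication control: screening limits, detection times, and
individualized withdrawal-time advice. This vignette is the package's
account of the science: the model and its assumptions, the estimation
machinery, the design choices that were genuinely open, and what the
synthetic experiments do and do not demonstrate.

## The structural model

Flunixin plasma kinetics are tri-exponential: a fast distribution phase
(half-life ≈ 1.4 h), an intermediate phase (≈ 3.8 h) that carries most
of the AUC, and a slow terminal phase (≈ 28 h) that only becomes visible
below a few ng/mL. The package parameterizes the mammillary
three-compartment model in clearances and volumes — `V1`, `V2`, `V3`
(mL/kg), plasma clearance `Cl` and intercompartmental clearances `Cl2`,
`Cl3` (mL/kg/h) — because those are the quantities with physiological
meaning and the ones the regulatory chain consumes. The micro-constants
are `k10 = Cl/V1`, `k12 = Cl2/V1`, `k21 = Cl2/V2`, `k13 = Cl3/V1`,
`k31 = Cl3/V3`; the exponential rates are the roots of the standard
characteristic cubic and the bolus coefficients follow from the
eigen-structure. `micro_to_macro()` implements the closed form rather
than an ODE solver because the Monte Carlo study evaluates hundreds of
thousands of curves; the test suite holds the closed form to within
1e-6 (relative) of a `deSolve` integration on random parameter sets.
Degenerate inputs (`Cl2 = 0` and/or `Cl3 = 0`) collapse analytically to
the bi-/mono-exponential solution — the corresponding exponential terms
are dropped, never epsilon-perturbed.

Urine is modelled as proportional to plasma:
`C_urine(t) = Rss · C_plasma(t)`, with `Rss` the pseudo-equilibrium
urine-to-plasma ratio (typical value 35.93). The proportionality is an
equilibrium statement and is only trusted from 24 h after the first
dose; `urine_concentration()` flags earlier values invalid, and the
fitting and detection-time machinery ignores flagged urine rows.
Multiple dosing is superposition of shifted bolus solutions, which the
linearity of the model licenses exactly.

Between-subject variability is log-normal, `θᵢ = θ_tv · exp(ηᵢ)` with
`η ~ N(0, Ω)` and a full 7 × 7 `Ω` (all covariances estimated; the
packaged matrix has, e.g., a 0.63 correlation between the clearance and
Rss effects). Variances are reported as CV% via
`100·sqrt(exp(ω²) − 1)`. Residual error is combined
proportional + additive per matrix:
`C_obs = f·(1 + ε₁) + ε₂`, with plasma σ_prop = 0.15, σ_add = 0.12
ng/mL and urine σ_prop = 0.42, σ_add = 0.11 ng/mL in the packaged
prior. The urine channel is genuinely noisy — 42% proportional error —
and several design decisions below follow from that.

## The synthetic cohort generator

No individual-level data from the source studies are redistributable,
so `generate_cohort()` is a first-class module that emulates the study
designs: six arms over four countries (10 + 10 Japanese mares at
1.1 mg/kg single and q24h × 5; 16 US Thoroughbreds at 1.1 mg/kg and 11
at a fixed 500 mg/horse; 6 UK Thoroughbreds; 12 Australian Standardbred
geldings), with each arm's published LOQs, age and body-weight ranges.
Fixed doses convert to ng/kg through each horse's drawn body weight.
Covariates are drawn independently and uniformly within the arm ranges —
deliberately effect-free, since the source analysis retained no
covariates.

Sampling schedules are not published. The defaults (plasma 0.083–168 h
post last dose on a 17-point grid; urine 24–168 h on 7 points) were
chosen once so that the observed granularity of cohort detection times
is representable; they are configurable per arm, and the pipeline adds
a 9 h point where the clinical "rich" scenario needs one. Below-LOQ
handling follows the source rule: `censor_loq()` removes below-LOQ rows
when they are under 5% of a matrix's observations and otherwise retains
them flagged; the likelihood excludes flagged rows either way (no M3
censored-likelihood term — with the rich schedules used here the
information loss is minor, and the rule mirrors the original analysis).

What passing tests on this generator do show: that the estimation and
detection-time machinery recovers the parameters and reproduces the
published population quantities *under the published generative model*.
What they cannot show: robustness to features real data have and the
generator lacks — assay-specific error structure, missed samples,
breed- or country-level systematic differences (the generator draws all
horses from one population), or departures from the proportional urine
model before equilibrium.

## Estimation

The source analysis used a proprietary QRPEM engine; the package's
contract is parameter recovery, not algorithm identity. `fit_population()`
implements the classical iterated two-stage EM with mode approximation:
the E-step computes each horse's posterior-mode `η` (bounded
quasi-Newton, |η| ≤ 6, with a derivative-free fallback for ill-scaled
likelihoods) and its Gauss–Newton curvature `F'WF + Ω⁻¹`; the M-step
shifts the typical values by the geometric mean of the modes, updates
the full `Ω` as the average of mode outer products plus conditional
covariances (projected to positive semidefinite by eigenvalue
clipping), and re-estimates the four residual σ's by direct likelihood
maximization (floored at 1e-4 so noise-free data remain finite). The
marginal log-likelihood is evaluated by the Laplace approximation at
the optimum, and `BIC = −2 ln L + k ln n`.

Starting values come from a noncompartmental pass
(`nca_initial_estimates()`: linear-trapezoidal AUC with IV
back-extrapolation to t = 0, terminal slope from the last ≥ 3 points,
`Cl = Dose/AUC∞`), with `Ω` initialized diagonal at 0.1. An optional
`polish` step re-maximizes the Laplace marginal directly over the
typical values; it is off by default because on the rich designs used
here the EM fixed point already sits on the Laplace-ML optimum (we
probed the surface numerically) and the step only adds minutes.

On 65-horse synthetic cohorts the estimator tracks each cohort's
*sample* geometric means to within a few percent; deviations from the
generating typical values are dominated by cohort sampling noise (with
a 99% CV on Rss, the geometric mean of 65 draws has a ~10% standard
error — a fact worth remembering when reading any 65-horse study).

Covariate screening is deliberately not a cascade of full NLMEM refits
(each candidate would cost minutes): `covariate_search()` regresses the
empirical Bayes `η`'s on the covariates — a power relation
(`log(cov/median)`) for continuous covariates, factor shifts for
categorical ones — and applies the published BIC thresholds: add above
6.635, delete below 10.823, and retain the final set only if it beats
the covariate-free model by ≥ 10.0. Covariates whose levels nest within
the country of origin (breed, in these designs) are reported as
confounded rather than selected. With low shrinkage (< 0.25 here) EBE
regression is a standard and honest screen; with sparse designs it
would lose power, which is a documented limitation.

Diagnostics follow pharmacometric convention: PRED (η = 0), IPRED
(posterior mode), conditional weighted residuals from a first-order
linearization around the EBE standardized by `FΩF' + Σ` (approximately
N(0,1) when the model is right — the suite checks mean within ±0.1 and
SD within [0.85, 1.15]), per-parameter shrinkage `1 − SD(η̂)/ω`, and a
visual predictive check with 500 simulated replicates summarized as
10/50/90 percentile bands (about 80% of observations should sit inside
the 10–90 band).

## The regulatory chain and detection times

`regulatory_limits()` implements the Toutain chain: for a daily dose of
1.1 mg/kg, `EPC = dose per 24 h / (Cl · 24) ≈ 968 ng/mL`; dividing by
the conventional uncertainty factor 500 gives `IPC ≈ 1.9 ng/mL`;
multiplying by the typical Rss gives the IUC. The published IUC figures
are mutually inconsistent at the rounding level (70.2 in one table,
68.4 in the text, 69.5 from the printed inputs), so the package asserts
only the confidence band, and integer rounding (2 and 70 ng/mL) is
applied solely at the screening-limit proposal step, never inside
computations.

Detection times are computed three ways, and the differences between
them are part of the science:

- `dt_ehslc()` is the cohort rule regulators quote: the earliest
  *scheduled* sampling time from which every horse in the trial is
  below the SL. It is grid-valued by construction and therefore snaps
  upward — it always dominates the per-horse estimates.
- `dt_interpolated()` mimics NCA practice: log-linear interpolation
  between the last observation at or above the SL and the first below
  it (linear fallback if a bracketing value is non-positive), measured
  from the last administration; horses that never reach the SL are
  censored-low (the "NC" of published tables).
- `dt_model()` solves `C(t) = SL` on the noise-free individual curve by
  bracketing and Brent root-finding to 0.01 h. After the last dose the
  curve is a sum of decaying exponentials, so the crossing is unique.

`mcs_population_dt()` draws 5000 η vectors from `N(0, Ω)` (continuous
DTs, not grid-snapped — the published quantiles are off-grid), computes
every horse's plasma and urine DTs for the shipped screening-limit set
(IFHA 1/100, candidates 2/70 and 3/100, HISA 4/100, RMTC 5/100 ng/mL),
and summarizes with type-7 quantiles at 5–95%. Urine DTs use each
horse's own sampled Rss, not the typical value. `dt_agreement()` gives
the per-horse plasma-minus-urine differences and Bland–Altman limits
(mean ± 1.96 SD). A deliberate modelling note: the simulated single-dose
quantiles reproduce the published ones closely, while the q24h × 5
plasma median comes out ~6% below the published figure; the multi-dose
DT is the quantity most sensitive to the tail behaviour of the η
distribution, and the published simulation conditioned on its fitted
per-horse η's, which are not available to re-draw from.

## Bayesian individualized withdrawal times

`map_estimate()` conditions the population prior on one horse's
samples: the posterior mode of η minimizes the residual negative
log-likelihood (matrix-specific combined error, σ's fixed at their
population values) plus the `N(0, Ω)` prior term. Two clinical
scenarios are built in: *rich* (plasma at 9, 24, 48 h after the last
dose plus urine at 48 h; a 72 h variant exists) and *sparse* (a single
plasma sample 24 h after the last dose — interpreted as 24 h after the
fifth dose for multiple dosing). `ibwt()` reads plasma and urine DTs
off the posterior-mode curves; `scenario_eval()` runs a whole cohort
and summarizes absolute errors against each horse's reference DT.

Two identifiability facts shape what to expect. First, four samples
cannot pin seven correlated random effects: even with noise-free
observations the posterior mode is the prior's choice on a
four-constraint manifold, and the plasma-DT error of the rich scenario
bottoms out around 6 h — near-zero error appears only in the degenerate
limit of zero between-subject variability. Second, under the published
42% urine noise the per-horse clearance effect is improved by the
posterior *on average*, but for horses with small |η_Cl| the posterior
can land on the wrong side of zero; the suite therefore asserts the
mean improvement and a 60% per-horse improvement fraction rather than a
near-certain one. Both facts match the source study's own experience
(rich-scenario mean absolute plasma-DT error of ~9 h on real data;
synthetic cohorts here give ~9 h as well).

## Numerical choices and problem sizes

- Root-finding tolerance 0.01 h for DTs; characteristic-cubic roots via
  `polyroot` with a complex-part guard; quantiles type 7.
- `Ω` is kept positive semidefinite by eigenvalue clipping at 0 (with a
  warning on user input, silently during M-steps); per-horse curvatures
  are inverted through an eigen floor of 1e-6.
- Residual σ's are floored at 1e-4 and residual variances at 1e-12 so
  degenerate noise-free inputs stay finite.
- MAP search: L-BFGS-B within |η| ≤ 6 (×400 on the parameter scale),
  Nelder–Mead fallback; infeasible parameter regions return a penalty
  that ramps with |η|² so searches are pushed back rather than stalled.
- Every stochastic entry point takes a seed; a fixed seed reproduces
  cohorts, Monte Carlo studies and pipeline artifacts byte-for-byte.
- Problem sizes: the test suite fits 65-horse cohorts (three seeds for
  the recovery experiment), runs the Monte Carlo study at its full
  n = 5000, uses 500 VPC replicates, and scales the bootstrap
  demonstrations down (5–12 replicates) since their contract is
  structural; a production bootstrap would use the conventional n = 50
  (`bootstrap_ci(n_boot = 50)`).

## Known limitations

- The estimator is an EM/Laplace scheme, not adaptive Gaussian
  quadrature; with very sparse designs or still larger residual CVs the
  mode approximation would degrade (the optional `polish` exists for
  such cases).
- Below-LOQ information is discarded rather than integrated (M3); with
  the packaged LOQs this is faithful to the source analysis but wastes
  some tail information.
- The urine model is a pure pseudo-equilibrium proportionality; urine
  flow, pH-dependent trapping and collection-interval pooling are not
  modelled, which is why pre-24 h urine is excluded outright.
- Oral or intramuscular absorption, the hydroxylated metabolite, and
  nonlinear clearance are out of scope.
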