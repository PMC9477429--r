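---
title: "Personalized AD biomarker-cascade modeling and optimal anti-amyloid therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized AD biomarker-cascade modeling and optimal anti-amyloid therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`adcascade` models Alzheimer's disease progression as a deterministic
cascade of five clinical biomarkers per subject: amyloid-beta burden
(`Abeta`), phosphorylated tau (`taup`), non-amyloid age-related tauopathy
(`tauo`), neurodegeneration (`N`, a normalized volumetric measure), and
cognitive impairment (`C`, an ADAS13-like score where higher is worse).
Amyloid grows logistically; amyloid drives p-tau production (saturating at
a p-tau capacity); age-related tauopathy grows linearly; both tau species
drive neurodegeneration, and neurodegeneration plus p-tau drive cognitive
decline, each with logistic saturation at a carrying capacity.

Assumptions worth making explicit:

* **Units are years everywhere in the model core.** All rates are per year
  and ages are in years. Clinical-trial rates quoted per week are converted
  at the drug-registry boundary (`rate/year = 52 × rate/week`; 78 weeks =
  1.5 years, 76 weeks = 76/52 years), so mixed-unit bugs cannot arise
  inside the solver.
* **Monotone progression.** Without treatment every state is
  non-decreasing (all rates are nonnegative); the model has no recovery or
  clearance mechanism except the treatment control acting on amyloid.
* **Model space, not assay space.** CSF amyloid-beta42 *decreases* with
  brain amyloid accumulation; the model state is brain-amyloid-like and
  *increases*. The transformation from raw assay values into model space is
  deliberately left to the user: all fitting operates on series already in
  model orientation. Which observed tau series maps onto `tauo` (total tau
  vs. total-minus-phosphorylated) is likewise a user decision.
* Subjects are independent; there is no hierarchical pooling.

Each subject is fully described by 11 rates/capacities, 5 initial
conditions, and a reference age `T0` at which the initial conditions apply
(`subject_parameters()`). `T0 = 50` is the default for all subjects: it
sits just below the youngest baseline age (54) found in the kind of
natural-history cohort this package emulates, so every subject's observed
window lies downstream of the reference age and treatment can be started
at any age ≥ `T0` after an untreated burn-in.

# Numerical core

All integration is classical fixed-step 4th-order Runge–Kutta on a uniform
age grid (default step 0.01 years), implemented in C++. A fixed shared
grid — rather than adaptive integration — is a deliberate choice: the
optimal-control solver must integrate states forward and adjoints backward
on the *same* grid, with states and controls linearly interpolated at RK4
half-steps. Controls are stored as grid-point values and interpolated
linearly between them. The untreated amyloid component has a logistic
closed form, which doubles as an oracle: the test suite requires grid-wise
agreement of the RK4 trajectory with the closed form to better than 1e-6
relative over 40 years (observed agreement is near machine precision), and
an endpoint step-halving check guards the integrator's order. States that
undershoot zero by less than 1e-12 (round-off) are clipped to zero; larger
undershoots abort with the offending age, as do non-finite states.

If a simulation window does not divide evenly by the step, the step is
adjusted to the nearest value that does, so both endpoints are always on
the grid.

# Per-subject calibration

The estimation problem — minimize the pooled squared deviation between the
simulated cascade and all observed biomarker points over all 16 subject
quantities — is non-convex, and a random start easily lands in poor local
minima. Because the cascade is triangular, the package instead warm-starts
from an equation-by-equation pass in cascade order:

1. amyloid: `(lambda_Abeta, K_Abeta, A0)` fitted with the logistic closed
   form;
2. p-tau: `(lambda_tau, K_taup, taup0)` with amyloid fixed;
3. tauopathy: `(lambda_tauo, tauo0)` (linear model);
4. neurodegeneration: `(lambda_N_tauo, lambda_N_taup, K_N, N0)`;
5. cognition: `(lambda_CN, K_C, C0)`;
6. joint refinement of all 16 quantities from the assembled start.

Every stage is a bounded Levenberg–Marquardt least-squares fit
(`minpack.lm::nls.lm`) with a small multi-start over growth-rate scales;
only the objective and the warm-start strategy are essential, not the
solver brand. Default box bounds: each rate in [0, 10 × its reference
group mean], each capacity in [max observed value, 10 × max observed],
each initial condition in [0, its capacity's upper bound]. The coupling
`IC ≤ capacity` cannot be expressed as a box constraint when both are
free, so it is enforced inside the model evaluation (ICs are clipped to
capacities), making the optimizer's model identical to the reported one.

Two details deserve explanation:

* **`lambda_Ctau` initialization.** The sequential pass estimates the
  cognition stage without the p-tau term (stage 5 fits only `lambda_CN`,
  `K_C`, `C0`), so `lambda_Ctau` enters the joint refinement with no
  sequential estimate. A start at exactly zero leaves a degenerate
  finite-difference Jacobian column, so the joint warm start seeds it from
  a coarse 1-D grid search over its bound range followed by a quick
  2-parameter (`lambda_CN`, `lambda_Ctau`) refit. This is initial-guess
  construction only; the joint fit estimates the parameter.
* **Degenerate series.** A series that is constant (to 1e-8 relative)
  carries no rate information — typically because the state saturated at
  its carrying capacity before the observation window. Such stages are
  flagged (`degenerate_stages`) and given the transparent convention
  rate = 0, initial condition = series mean, capacity = observed plateau,
  rather than arbitrary interior values from a flat likelihood.

The residual-weighting question is genuinely open: the biomarker series
differ by orders of magnitude (neurodegeneration is ~1, amyloid ~260), so
an unweighted pooled objective is dominated by the large-scale series. The
default here is unweighted — the plainest reading of a pooled
least-squares objective — with an optional per-biomarker `weights`
argument; `1/max(series)` weights are what the package's own recovery
tests use, since without them the small-scale series sit below the
optimizer's resolution in the pooled objective.

The per-biomarker goodness-of-fit is reported as mean relative error. The
default form is the mean absolute relative deviation
`mean(|model−obs|/|obs|)` with `form = "rmsre"`
(`sqrt(mean(((model−obs)/obs)^2))`) available, since published renderings
of this statistic are ambiguous between the two; the reported
`relative_errors` field is exactly the chosen formula applied to the
training data.

Subjects require at least three datapoints per biomarker; otherwise they
are excluded with an explicit machine-readable reason (condition class
`adcascade_exclusion`), never silently dropped.

## What parameter recovery can and cannot show

Generate-and-refit experiments (the package's main validation tool) only
measure parameters the data can see. Under the bundled group profiles, the
cognition dynamics are fast enough that `C` reaches its capacity before
age 54 for most sampled subjects — the observed cognition series is then a
flat plateau, and `lambda_CN`, `lambda_Ctau`, `C0` (and sometimes the
neurodegeneration stage) are structurally unidentifiable no matter how the
optimizer performs: the fit is exact and the flagged parameters are
arbitrary. The test suite therefore validates full 16-parameter recovery
on an identifiable-regime subject (every state traverses most of its
dynamic range inside a long, dense observation design, and the three
cognition/neurodegeneration drivers have distinguishable shapes), and
separately validates that saturated series are flagged rather than fitted.
Similarly, the sampling spread of any estimator is bounded below by the
information in the design: six amyloid points over a 10-year window under
5% multiplicative noise leave a median relative error around 17–19% for
the amyloid growth rate (the estimator is unbiased to a few percent); no
optimizer can beat that floor.

# Treatment optimization

Anti-amyloid therapy enters the amyloid equation as a clearance term
`−u(t)·Abeta` with `0 ≤ u(t) ≤ u_max`. The objective on a treatment window
`[T1, T2]`,

`J(u) = alpha1·Abeta(T2) + alpha2·C(T2) + ∫ C dt + ∫ eps(Abeta,t)·u² dt`,

penalizes end-of-treatment amyloid and cognition (weights
`alpha1 = alpha2 = 1` by default), the accumulated cognitive burden, and
side effects. The side-effect weight `eps = eps0·Abeta·e^{−gamma·t}`
reflects that ARIA-like events are most likely at high amyloid burden and
early in treatment; `t` is measured from treatment start (not absolute
age), and `gamma` is per year. The defaults `eps0 = 5`, `gamma = 2` follow
the published calibration of these constants against the dose-ramp
schedules of the aducanumab trials; that calibration's printed arithmetic
is not reproducible under any consistent unit reading, so the two values
are adopted as plain configuration defaults rather than re-derived.

Pontryagin's maximum principle yields a five-equation adjoint (costate)
system integrated backward from the transversality conditions
`L1(T2) = alpha1`, `L5(T2) = alpha2`, rest zero, and the interior
stationarity condition `u = L1·Abeta/(2 eps)`. Two printed-form issues are
handled explicitly:

* The control characterization is implemented in the standard clamp order
  `min(u_max, max(0, ·))` — the only order consistent with the admissible
  set (the reversed order would always return `u_max`).
* The full derivative `−∂H/∂C` contains a `lambda_Ctau·taup/K_C` feedback
  term that commonly quoted reduced forms drop. The derived (full) form is
  the default; `adjoint_form = "printed"` reproduces the reduced system.
  The finite-difference gradient check in the test suite holds for the
  derived form (to ~1e-5 relative; tolerance 1e-3) and is how the two were
  adjudicated.

The optimality system is solved by a forward–backward sweep: starting from
`u ≡ 0`, iterate forward state solve, backward adjoint solve, pointwise
control update, and a relaxed convex combination `u ← relax·u_new +
(1−relax)·u_old` (default `relax = 0.5`). Convergence is declared when the
maximum over the three blocks (states, adjoints, control) of
`‖new − old‖∞ / (‖old‖∞ + 1e-12)` drops below `tol = 1e-4`; the iteration
cap is 500 and non-convergence is returned as a flag, never hidden. If the
objective rises for five consecutive sweeps the relaxation weight is
halved (logged via `message()`) — this engages on long treatment windows
and restores monotone progress.

The sweep is validated two independent ways: (i) the adjoint-based
gradient matches central finite differences of the objective; (ii) on a
coarse 8-interval grid, the sweep objective matches a direct multi-start
L-BFGS-B optimization over the same discretized control space to well
under 1%. The direct optimizer deliberately uses the sweep's own control
parameterization (grid-point values, linear interpolation): on so coarse a
grid a piecewise-constant control class would differ by discretization
alone, and the comparison is meant to check the optimizer, not the
discretization.

# Drug registry

Published trial outcomes are converted to maximum clearance rates under
constant maximal dosing, where the amyloid equation reduces to exponential
decay: a fraction `f` of baseline remaining after `d` weeks gives
`u_max = −ln(f)/d` per week. Built-in agents: aducanumab low dose (16.5%
reduction at week 78 → 2.31e-3/week), aducanumab high dose (27.2% →
4.07e-3/week), and donanemab (amyloid PET SUVr reduced by 84.13 from a
baseline of 107.6 — read as an absolute decrease, so 23.47 remaining —
over 76 weeks → 2e-2/week). Rates are derived from the source observations
at load time, not stored as rounded constants; only the dimensionless
fraction of the SUVr values is used, so no assumption is made about the
PET scale matching the model's amyloid units.

# Synthetic cohorts

The generator emulates the sampling design of a multicenter
natural-history study: CSF-like biomarkers every 2 years up to 10 years (6
visits), volumetrics yearly (11 visits), cognition every 6 months (21
visits), baseline ages uniform on [54, 85], at least three points per
biomarker. Ground-truth parameters are drawn per group (AD n = 10, LMCI
n = 32, CN n = 7 by default) from independent truncated normals at the
published group means/standard deviations — truncated below at 1e-6 (to
keep the cascade well-posed) by inverse-CDF sampling rather than clipping,
which would pile mass at the floor for wide-spread rates; initial
conditions are additionally truncated at the subject's sampled capacity.
No between-parameter correlations are modeled (none are published).
Observation noise is multiplicative Gaussian with per-biomarker
coefficients of variation, default 5% for the CSF-like series, 1% for
volumetrics, 10% for cognition — chosen once to match the order of
magnitude of typical reported fitting errors for those biomarker classes.

What the generator does **not** emulate: dropout and irregular visit
attendance, assay batch effects and re-baselining, left-censored CSF
values, correlated parameters, diagnosis-dependent baseline ages, and the
assay-to-model-space transformation. Passing recovery tests on synthetic
cohorts therefore demonstrate the correctness of the estimation machinery,
not the fidelity of fits to real cohort data. Note also (see above) that
group-mean dynamics put cognition at its ceiling within the observed
window for most sampled subjects, which is itself a caution about taking
the published group means as a literal generating process.

# In-silico trials

A trial arm is a drug, a start age (60 and 70 conventionally), a duration
(78 weeks or 10 years), and an optimal-control configuration. For every
subject the package simulates the untreated trajectory from `T0`, solves
the personalized control problem on the treatment window, and reports the
cognitive percentage change at end of treatment,
`(C_treated − C_untreated)/C_untreated × 100`; tables show the negated
value so positive numbers mean less decline, and the maximum effect over
the treatment course is reported alongside. Subjects with `|change| <
1e-7` are "no response" (NR): rendered literally as `NR` in wide-format
tables and contributing zero change to the arm median (the handling is a
convention and is documented as such; non-convergent sweeps are instead
excluded from the median and counted). Under ceiling saturation the
percentage change at `T2` of a long arm can be *smaller* than that of a
short arm — both treated and untreated cognition sit at capacity by the
later endpoint — so duration orderings are only informative for subjects
whose cognition is still evolving, as the trial-runner tests demonstrate
with a non-saturating subject.

# Problem sizes and runtime choices

The bundled tests and the acceptance script use: integration step 0.01
years (0.02 for 10-year trial arms and cohort-level sweeps), a 10-subject
synthetic cohort for recovery and trial-structure runs, 20 noise
replicates for the estimator-noise study, and an 8-interval coarse grid
for the direct-optimization cross-check. These sizes were chosen so the
full pipeline (generate → calibrate → optimize) runs on a laptop-class
single core in seconds to a few minutes while leaving the conclusions
unchanged under grid refinement (the step-halving test pins the
integrator's accuracy independently).

# Known limitations

* The model is a deterministic, spatially aggregated caricature: no
  stochasticity, no spatial/network spread, no pharmacokinetics — the
  control is an instantaneous clearance rate, not a dosing schedule in
  mg/kg.
* Calibration quality is bounded by identifiability; the package flags
  degenerate stages but cannot conjure information the design does not
  contain.
* The sweep finds controls satisfying the necessary optimality conditions
  and matching discretized direct optimization; no global-optimality
  certificate is attempted.
* Group profiles ship as independent normals; real parameter vectors are
  correlated, so synthetic cohorts are wider than real ones in some
  directions.
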