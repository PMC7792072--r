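---
title: "Designing and simulating staged multi-arm platform trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating staged multi-arm platform trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platformtrial)
```

## The design problem

A platform trial keeps a single protocol open while experimental arms enter
and leave against one or more shared control arms. The statistical design
questions this package addresses are the ones such a programme must answer
before any amendment is approved:

* how many events and participants each comparison needs;
* how an event-driven interim analysis changes the per-look significance
  thresholds;
* whether dynamic randomisation (minimisation), reset whenever the arm set
  changes, still balances the stratification factors;
* which patients may contribute to which comparison once arms have opened
  and closed at different times (*concurrent comparators*); and
* what the whole machine's operating characteristics are — per-hypothesis
  type-I error, power, and the family-wise error across hypotheses that
  share control patients.

The bundled `flair_design()` fixture is a three-stage, four-arm
chronic-lymphocytic-leukaemia configuration (control chemo-immunotherapy
FCR throughout; an experimental arm IR that completes recruitment mid-way;
a second control I and an experimental doublet I+V added at the same
moment) with two survival hypotheses against the shared FCR control and
one binary minimal-residual-disease (MRD) hypothesis between the late
arms. Everything below generalises to any `design_spec()`.

## Models and assumptions

**Survival.** Event (progression/death) times are exponential per arm,
parameterised by the median; a hazard ratio between two arms is then the
inverse ratio of medians. This is the standard design-stage assumption —
sample-size formulas, the event-probability integral and the simulator all
share it, so the simulation verifies the design under exactly the model
the design was computed from. Real PFS curves are not exponential; the
package makes no claim about robustness to non-proportional hazards (see
Limitations).

**Accrual and dropout.** Entry is a homogeneous Poisson stream at
`accrual_rate` patients/year (uniform accrual in expectation, matching the
event-probability integral). Dropout is independent exponential censoring
calibrated so that the probability of dropping out within the
`dropout_horizon` (default: the longest accrual + follow-up span among the
hypotheses) equals `dropout_prob` — the design documents only a dropout
*proportion*, so a memoryless process calibrated to that proportion is the
least-structured choice consistent with it.

**Binary endpoint.** MRD negativity is Bernoulli per arm, independent of
the survival time. In reality MRD status and progression are linked
(MRD-guided therapy-duration rules confound the two); that mechanism is
deliberately out of scope, and the binary endpoint should be read as "a
second, independent primary endpoint".

**Stratification factors.** Independent draws per factor; the fixture uses
disease stage (2 levels), age group (2), sex (2) and centre (100 levels,
standing in for "all participating centres" — the exact centre list is
irrelevant to the statistics, only its cardinality matters for the
randomiser).

## Sample size

`required_events()` implements Schoenfeld (default) and Freedman. The
defaults reproduce the fixture's printed targets: 379.35 events for a
hazard ratio 0.75 at two-sided 5% and 80% power, and 232.18 events at the
exact median ratio 4.5/6.5 — evidence that the original calculations used
Schoenfeld on the unrounded ratio, since the rounded 0.69 gives 228.0.
Freedman is uniformly at least as large for hazard ratios below 1 (a
property test covers 0.5–0.9).

`required_n()` divides events by the allocation-weighted mean event
probability and inflates by 1/(1 − dropout), rounding the total up to a
whole allocation block. For the fixture's original two-arm stage this
yields 732 against a stated 754 (−2.9%), and 268/arm against a stated 274
(−2.2%) for the amended comparison. Design documents rarely state their
software's accrual, rounding and inflation conventions; the package's own
conventions are: ceiling after all inflation, uniform accrual exactly over
the stated window, no group-sequential inflation unless requested. The
group-sequential information inflation factor (1.0078 for the two-look
plan) is available from `obf_boundaries()` and can be passed to
`required_events(gsd_inflation =)`; the stated 379 is consistent with *no*
inflation, so that is the default.

`binary_power()` uses the pooled-variance z-test normal approximation (no
continuity correction), the variant that reproduces the stated 90% at
260/arm for 10% → 20% (0.894) and 20% → 32.5% (0.902). `exact_sim`
estimates the same power by binomial simulation and agrees within
Monte-Carlo error.

## Group-sequential boundaries

`obf_boundaries()` computes the classic O'Brien–Fleming efficacy boundary:
constant on the score scale, so z_k = C/√t_k at information fraction t_k.
The crossing probability of the correlated Gaussian increments is computed
by the classical recursion — the density of the score process confined
within the continuation region is propagated look to look by numerical
convolution — using composite Simpson weights. Numerical choices: the
integration grid spans the continuation region, is never coarser than a
quarter of the smallest increment's standard deviation, and is refined
(256 → 4096 nodes) until the boundary moves by less than 1e-5; the
boundary constant is then solved by `uniroot` to 1e-8.

For a single interim at half the information, the nominal two-sided
p-value thresholds are 0.005166 and 0.047993 — the familiar 0.005 / 0.048
pair. Three-look boundaries were verified against an independent
Monte-Carlo of the Brownian score process (10⁶ paths during development;
2 × 10⁵ in the shipped test).

Two shapes are provided because the field uses both: the classic
constant-C boundary (default; it reproduces the printed two-look pair) and
the O'Brien–Fleming-like alpha-spending function
α*(t) = 2 − 2Φ(z₁₋α/2/√t), which differs slightly at the interim (0.0056
vs 0.0052). Only efficacy (early-rejection) boundaries are implemented —
no futility or beta-spending, mirroring designs that reserve interim
looks for strong evidence of benefit.

## Minimisation with a random element

`assign_minimisation()` implements the Pocock–Simon range variant: the
candidate arm's score is the count of patients sharing the new patient's
level on each factor already on that arm (including the candidate),
normalised by the allocation weight and summed over factors; the minimiser
is followed with probability p, otherwise one of the remaining arms is
chosen uniformly, ties among minima broken uniformly first. The random
element defaults to p = 0.8 — operational descriptions of such systems typically confirm a random
element without stating its value, and 0.8 is the common choice; it is an explicit `design_spec` field, not a constant.
All four factors, including the 100-level centre, carry equal weight (no
weighting is documented anywhere; equal weights are the default in
practice).

At every stage transition the algorithm is **reset** — carrying counts
forward would score any newly added arm as maximally under-represented and
funnel patients into it. Resetting is idempotent and leaves each stage's
concurrent cohort internally balanced.

The sequential assignment loop is compiled (`src/recruit.cpp`) and shared
between the single-step API and the trial engine, so the two are
bit-identical under the same RNG stream.

## The staged trial engine and concurrency

`run_trial()` walks the patient stream: each patient is randomised under
the stage open at their entry; a stage's entry trigger (cumulative
recruitment count of a named arm, or calendar time) is evaluated before
every randomisation, and the recruitment stop rule after stage
transitions. The fixture encodes its stage targets as counts: stage 2
opens when IR reaches 316, stage 3 when IR reaches its 377 target, and
recruitment stops when 274 control patients have been randomised
concurrently with the doublet. Those three numbers imply ~61 stage-2
control patients — the shared controls — and totals within a patient or
two of the stated 754 / 822 / 1516 (the stated totals themselves
differ by one from their own decomposition; the fixture keeps the printed
numbers and leaves the single-patient discrepancy unresolved, as noted in
its comments).

**Concurrency rule.** A patient belongs to a hypothesis's analysis set iff
both of its arms were open to allocation at the patient's randomisation
*and* the patient was randomised to one of them. "Open at randomisation"
operationalises contemporaneity by randomisation order; nothing else about
the calendar matters. Shared controls are control-arm patients in two or
more sets.

`analysis_dataset()` censors every concurrent patient administratively at
the analysis cutoff — a calendar time, or the calendar time of the d-th
concurrent event for event-driven interims (the cutoff-defining event is
kept in the count despite floating-point round-trip, hence the 1e-9
tolerance in the event indicator). Event-count cutoffs are computed on the
comparison's own concurrent patients, since the interim is defined on the
comparison's information.

**Reproducibility.** One seed drives entry times, profiles, assignments
and outcomes. Outcomes are drawn by inverse transform from per-patient
uniforms indexed by entry order, so changing one arm's true parameters (a
scenario override) rescales only that arm's outcome draws and perturbs no
other patient — a variance-reduction and debugging property worth the
small indirection.

## Analyses

`logrank()` is the standard observed-minus-expected statistic with
hypergeometric variance, returned with its signed normal deviate. `fit_ph()`
maximises the Breslow partial likelihood by Newton–Raphson with
step-halving; standard errors from the inverse observed information; the
global score test at the null reproduces the log-rank chi-square for a
single binary covariate (asserted to 1e-8 in tests) and the fitter matches
an established survival library to better than 1e-4 on random fixtures.
Breslow tie-handling was chosen because simulated continuous times are
almost surely tie-free, while imported real data may tie — Breslow is the
convention whose partial likelihood the recursion evaluates cheaply.
Monotone-likelihood divergence (all events on one arm) and
non-convergence are flagged, never returned silently.

`fit_logistic()` (IRLS) carries the same structure for the binary
endpoint, including an efficient score test that reduces to the
pooled-variance two-proportion chi-square in the intercept + arm model,
and separation detection.

Regression covariates follow the design's analysis plan: treatment, trial
stage (categorical) and the stratification factors *except centre* — 100
centre levels would destabilise any of these fits, and the plan's stated
covariate list is disease stage, age group and sex plus trial stage.

## Operating characteristics

`evaluate_oc()` simulates the full design under a scenario of true per-arm
parameters and applies each hypothesis's group-sequential boundaries at
its event-driven looks. Within the Monte-Carlo loop the default test is
the log-rank score test; `analysis = "cox"` switches to the
covariate-adjusted Wald test at roughly five times the cost (the two agree
under randomisation; the score route is the speed choice for calibration
runs, the regression route the fidelity choice for stage-effect
scenarios).

Three family-level quantities are reported:

* **FWER** across the hypotheses sharing the control arm (default family:
  the two survival comparisons against the common control). Sharing ~61
  control patients induces a small positive correlation (~0.08) between
  the two z-statistics; for two-sided tests the induced reduction of the
  FWER below the independence bound 1 − (1 − α)² = 0.0975 is second-order
  in that correlation — real, but of order 2 × 10⁻⁴ here, so
  distinguishing it empirically from the bound itself needs very large
  simulations. The report therefore also includes an *independence
  coupling* estimate (first hypothesis's rejections paired with the next
  replicate's second hypothesis) with identical marginals, for a
  like-for-like comparison from the same replicates.
* **Intersection-union success** (all of a set of hypotheses significant,
  the rule used when one arm must beat two comparators): its size never
  exceeds the component level, with the least favourable configuration —
  truly null against one comparator, decisively superior on the other —
  exercised in the acceptance tests.
* **Statistic correlation** between the family hypotheses.

Problem sizes used by the shipped tests: 10⁴ replicates for the
calibration claims (null rejection 0.05 ± 3 MC SE, intersection-union
non-inflation, FWER below 0.0975), 200–400 replicates for the structural
properties (correlation sign, power ordering), chosen so each claim's
Monte-Carlo standard error is small against the margin it must resolve.

## Known limitations

* Exponential survival and proportional hazards throughout; no cure
  fractions, no non-proportional alternatives, no sample-size
  re-estimation.
* MRD response independent of survival; MRD-guided treatment dynamics not
  modelled.
* No futility boundaries; no per-centre recruitment heterogeneity; no
  response-adaptive allocation.
* The FWER reduction from shared controls is verified in sign and bound,
  not estimated to its (second-order) magnitude.
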