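---
title: "Simulating pilot bioequivalence trials and comparing decision methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pilot bioequivalence trials and comparing decision methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilotbe)
library(dplyr)
```

## The problem

A pilot bioavailability/bioequivalence (BA/BE) study is a small 2×2×2
crossover trial — two sequences (TR, RT), two treatments (test and
reference), two periods — run to judge whether a candidate formulation
deserves a pivotal bioequivalence study. The conventional analysis is
average bioequivalence (ABE): conclude bioequivalence when the 90%
confidence interval of the test/reference geometric least-squares mean
ratio (GMR) of a log-normal pharmacokinetic metric lies within
[80.00, 125.00]%. With 12–18 subjects this criterion is extremely sensitive
to within-subject variability: a truly bioequivalent product can fail
simply because the interval is wide, and the pilot's answer becomes noise.

`pilotbe` provides a seeded Monte-Carlo laboratory for this situation: a
population-pharmacokinetic trial simulator with known ground truth, four
decision rules applied to the same simulated trials, and a
confusion-matrix harness that turns repeated verdicts into sensitivity
(power), specificity (1 − type I error) and agreement statistics. All
decisions are made on Cmax: of the two standard metrics it is the one most
exposed to sampling-time and variability artefacts, so it is where a
pilot's conclusion is most fragile.

## Simulation model

**Structural model.** One-compartment disposition with first-order
absorption and elimination, parameterized with micro constants. The
closed-form (Bateman) solution

$$C(t) = \frac{F\,D\,k_a}{V\,(k_a-k_e)}\left(e^{-k_e t}-e^{-k_a t}\right)$$

is used for speed; it is mathematically identical to integrating the
two-state mass-balance ODE system, and the test suite verifies agreement
with a stiff ODE solution to a relative tolerance of 1e-6 together with
mass balance of the ODE oracle. When `ka == ke` (within 1e-10 relative)
the analytic limit $C(t)=F D k_a t\,e^{-k_a t}/V$ avoids the 0/0. Doses
are in mg and volumes in L, so a factor of 1000 converts to µg/L.

**Defaults.** ka = 1.22 h⁻¹, V = 58.8 L, ke = 0.15 h⁻¹, F = 0.9, dose =
50 mg, sampled at the fixed 20-point schedule 0, 0.25, …, 4, 6, 8, 12,
24 h (`be_sampling_times()`; note there is deliberately no 1.25 h point).
On this grid the noise-free reference profile peaks at 570.4 µg/L at the
2 h sample.

**Statistical model.** Individual parameters are log-normal:
$\Psi_{ij} = \bar\Psi\, e^{\eta_i + \kappa_{ij}}$ with $\eta_i \sim
N(0,\omega^2)$ per subject (inter-individual variability, IIV) and
$\kappa_{ij} \sim N(0,\gamma^2)$ redrawn per occasion/period
(inter-occasion variability, IOV). Variability is applied to **exactly one**
parameter at a time (`varying`); bioavailability F never varies. Observed
concentrations carry a multiplicative log-normal residual error
$Y = C\,e^\varepsilon$, $\varepsilon \sim N(0,\sigma^2)$, drawn
independently per sample; the pre-dose sample is exactly zero, which the
multiplicative model preserves.

**Variability convention.** The stated percentages are used directly as
log-scale standard deviations: ω = IIV%/100, γ = IOV%/100, σ =
residual%/100 (the convention of mixed-effects simulation engines). The
alternative exact-CV mapping ω = √ln(1+CV²) differs by <1% at 10% and
~4.5% at 45%; we keep the direct convention for the simulator because it is
what mixed-effects simulation engines implement. The **analysis-side** mapping is
deliberately different: TOST power/sample size converts an intra-subject CV
via σ_w = √ln(1+CV²), because that is the exact inverse of the ISCV
estimator `ISCV% = 100·√(exp(MSE)−1)`, so sizing from an estimated ISCV
round-trips.

**Truth groups.** A truly bioequivalent test product shares all parameter
means with the reference; a truly bioinequivalent one has its mean ka
multiplied by 0.3 (slower absorption: later, ~28% lower continuous peak,
identical total exposure since F, V, ke are unchanged). No sequence,
period or carryover effects are simulated; the 7-day washout is metadata.

**Randomization.** Balanced block-wise lists with a block size of 2 (the
smallest balanced block; the design prescription says only "balanced
block-wise"), one subject of each sequence per block in random order.

**Seeding.** Every simulation function takes an optional seed and restores
the caller's RNG state. The experiment runner derives a deterministic
sub-seed per trial from the master seed and the cell coordinates, so cells
can be run in any order — or singly — with identical results.

## Decision methods

**ABE.** Fixed-effects crossover ANOVA of ln(Cmax) with sequence, subject
nested within sequence, period and treatment effects. Subject is fixed, as
in the classical bioequivalence analysis; no mixed-model option is
offered. For complete data the fit collapses to the paired contrast: the
treatment effect is half the difference of the sequence-wise mean period
differences, MSE is half the pooled variance of those differences, df =
n − 2, and se = √(MSE/2·(1/n₁+1/n₂)). This closed form is the default
(and is what the bootstrap loop uses); a full least-squares path
(`method = "lm"`) exists and the suite proves both identical to 1e-10
against an independently built normal-equations oracle, also under
unequal sequence allocation. Subjects missing a period are excluded with
a warning; fewer than 3 complete subjects is an error. Acceptance bounds
are compared at full floating precision, inclusively.

**Centrality.** GMR point estimate inside [90.00, 111.11]%. The upper
bound is taken as conventionally stated rather than 1/0.9 = 111.1̄%; at two-decimal
comparison the difference is immaterial.

**Bootstrap.** The original trial's ANOVA gives the ISCV; the resample
size is the exact TOST sample size at that CV assuming a true GMR of 0.90,
80% power, α 0.05 — forced even, minimum 4, and *not* capped at the
original n (resampling with replacement permits larger resamples; capping
would mask the method's documented type-I inflation). Each of B = 100
resamples draws resample_n/2 subjects with replacement per sequence; drawn
subjects contribute both periods and are relabeled as distinct
pseudo-subjects so the fixed-effects ANOVA stays full rank when a subject
recurs. The 95% bounds are the empirical 2.5/97.5 percentiles with linear
interpolation between order statistics (R's default type 7 quantile — the
rule is pinned because definitions differ slightly at B = 100); the
bootstrap standard error is reported but takes no part in the decision.

**ƒ2 similarity.** Test and reference mean profiles (arithmetic or
geometric; the geometric mean is defined as 0 whenever a contributing
value is 0, which under this simulator happens only at t = 0) are
normalized to the *reference* mean profile's Cmax and truncated at the
reference mean tmax — each mean type uses its own reference peak, and peak
ties break to the earliest grid time. Then

$$f_2 = 50\,\log_{10}\!\Big(100\,\big(1+\tfrac1n\textstyle\sum_t (R_t-T_t)^2\big)^{-1/2}\Big)$$

with decision f₂ ≥ θ for θ ∈ {35, 41, 50}. The t = 0 point is included in
n by default (the normalization window is 0 ≤ t ≤ tmax_ref and both
normalized values are exactly 0 there); `include_t0 = FALSE` is available
since the original count is ambiguous — including it raises f₂ slightly
because it contributes a zero difference. No dissolution-style
applicability guards (early-point CV limits) are imposed.

**Exact TOST power.** The probability that both one-sided t-tests reject
is computed from the bivariate noncentral t via Owen's Q function,
integrated numerically with the chi kernel evaluated on the log scale (no
overflow at large df) and the upper limit truncated where the kernel's
mass is exhausted (chi quantile at 1e-14), which keeps `integrate()`
honest when the theoretical limit is astronomically large at tiny CV. A
noncentral-t difference approximation is provided and cross-validated; it
is accurate at moderate-to-high power but truncates at zero below, so the
exact path is always the default. Sample-size search is doubling followed
by bisection over even n. At a true GMR exactly on an acceptance limit
the power correctly collapses to the test's size (≤ α). No pilot floor of
12 subjects is applied inside the search — the floor belongs to the
trial-design grid, not the mathematics.

**Performance.** Verdicts against ground truth accumulate into TP/FN/FP/TN
and eight statistics. Cohen's κ uses the standard two-class form
`2(TP·TN−FP·FN)/((TP+FP)(FP+TN)+(TP+FN)(FN+TN))`, which reproduces the
expected agreement values on reference confusion matrices. Statistics with zero denominators are
reported as `NA` with a `degenerate` flag — never silently zero.

## Non-compartmental analysis

Cmax is the maximum observed concentration, tmax its earliest time. AUC to
the last sample uses the linear-up/log-down trapezoid: linear when the
concentration rises or touches zero, logarithmic — exact for
mono-exponential decline — otherwise. The pure linear trapezoid (available
via `method = "linear"`) inflates the sparse 8→12→24 h tail of this
schedule by ≈4%, incompatible with the simulated baseline AUC0–24 of
≈4.95×10³ µg·h/L that the log-down rule reproduces within noise. No
extrapolation to infinity and no below-limit-of-quantification handling:
the generator produces none.

## What the generator does and does not emulate

It emulates: crossover design with balanced randomization; log-normal
IIV/IOV on one parameter; log-normal assay/sampling error; a fixed rich
sampling schedule; a pure absorption-rate difference as the
bioinequivalence mechanism. It does **not** emulate: multi-compartment or
nonlinear kinetics, absorption lag, sequence/period/carryover effects,
dropout, missing samples, or quantification limits. Passing tests
therefore demonstrate the decision methods' behaviour under idealized
variability structures, not robustness to real-data pathologies such as
sparse sampling near the peak or informative dropout.

## Problem sizes and tolerances in the test suite

The package's own verification uses desk-scale versions of the study
design: moment-recovery checks with 5,000 simulated subjects, 100 random
parameter sets against the ODE oracle (rtol 1e-6), ANOVA equivalence to
1e-10, exact-vs-Monte-Carlo TOST power within 3 Monte-Carlo standard
errors at 50,000 simulations, and operating-characteristic cells of 100
trials (the per-cell replication of the full design) for the simulated
sensitivity/specificity checks, with 3 binomial standard errors as the
acceptance band. The full 32,000-trial grid is a single
`run_experiment(experiment_plan())` call and is reproducible from its
master seed, but no routine check requires it.

## Known limitations

* The fixed-effects ANOVA (subject as fixed) matches the classical
  analysis but cannot exploit replicate designs or partial data the way a
  mixed model would.
* The bootstrap's percentile rule and pseudo-subject relabeling are the
  natural full-rank choices, but other implementations may differ in the
  percentile definition and in whether duplicated subjects share an ANOVA
  level; at B = 100 those choices move the bounds by fractions of a
  percentage point.
* ƒ2 on Cmax-normalized mean profiles compares *means*, so it cannot
  detect subject-level distributional differences that leave the mean
  curves similar.
* The direct percent/100 convention for ω and γ means the realized CV of
  a 45% random effect is ≈47%; consumers who need exact-CV effects can
  pre-transform the inputs.
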