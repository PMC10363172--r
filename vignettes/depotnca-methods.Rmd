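---
title: "Methods: simulation and noncompartmental analysis of extended-release depot studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and noncompartmental analysis of extended-release depot studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depotnca)
```

## The problem

Long-acting buprenorphine depots are dosed subcutaneously in laboratory
primates so that plasma concentrations stay above a putative analgesic
threshold (0.1 ng/mL) for days rather than hours. Studies characterising such
formulations are necessarily sparse: a few animals per dose group, about
seven venipuncture samples over 72 h, an assay LLOQ of 0.1 ng/mL, and a
metabolite (norbuprenorphine) of safety interest. The analysis standard in
this field is noncompartmental: parameters are read off or integrated
directly from each animal's concentration–time series, groups are summarised
as mean ± SD, and formulations are compared with small-sample nonparametric
tests.

`depotnca` implements that pipeline, together with a simulator that emulates
the study design, because individual-animal concentrations from such studies
are generally not published: every stage of the analysis is exercised and
verified on synthetic data with known truth.

## The simulator

### Mechanistic form

Extended-release depots show a rapid initial rise (quantifiable within
15 min) *and* multi-day persistence. The minimal mechanism producing both is
the superposition of two first-order absorption depots feeding one
disposition compartment — a fast depot for the onset and a slow one for the
sustained phase. Each depot contributes a Bateman term; the single-depot
model is the special case `frac_fast = 1`. The closed form is singular when
an absorption rate equals the elimination rate `ke = CL/V`; construction
nudges the absorption rate by a relative 10⁻⁹ (with a message) when
`|ka − ke|/ke < 10⁻⁹`.

Whether marmoset depot profiles are truly biphasic in absorption cannot be
decided from group-level means; the simulator exposes both one- and
two-depot forms without claiming mechanistic fidelity. If the slow depot is
slower than elimination (`ka_slow < ke`) the model exhibits flip-flop
kinetics: the observed terminal slope is `min(ke, ka_slow)`, and the
simulator records that value — not `ke` — as each subject's true terminal
rate.

### Default parameter values

The defaults (all overridable via `population_params()` or the JSON config)
were chosen once, by calibrating the noise-free model to the magnitudes
reported for extended-release buprenorphine in marmosets:

| parameter | default | unit | rationale |
|---|---|---|---|
| CL/F | 1.8 | L/h/kg | reported clearances ~1.7–2.3 L/h/kg |
| V/F | 55 | L/kg | with CL/F gives ke = 0.0327 h⁻¹, t½ ≈ 21 h (reported 21–37 h) |
| ka_fast | 0.9 | 1/h | quantifiable (> 0.1 ng/mL) by 0.25 h at all doses |
| ka_slow | 0.12 | 1/h | Tmax ≈ 8.6 h (reported ~6–13 h); > 0.1 ng/mL at 72 h |
| frac_fast | 0.5 | — | equal split; keeps both phases visible |
| BSV CV | 0.3 (CL, V), 0.5 (ka) | — | produces group SDs comparable to published tables |
| residual CV | 0.15 | — | typical LC–MS/MS plasma assay precision |
| fm, Vm/F, ke_m | 0.35, 60 L/kg, 0.05 h⁻¹ | — | metabolite quantifiable from ~8 h through 72 h |

At these values the noise-free model gives Cmax 1.21 / 1.81 / 2.42 ng/mL at
0.1 / 0.15 / 0.2 mg/kg — inside the reported 1.4–2.5 ng/mL band and
dose-proportional. These are calibration conveniences that make the synthetic
study *look like* the real one; they are never used as evidence about real
data.

### Statistical structure

Between-subject variability is log-normal with the typical value as the
population median (`sdlog = sqrt(log(1 + cv²))`), which preserves positivity
of all rates and volumes. Residual error is proportional log-normal with
median 1, so its coefficient of variation equals the configured `residual_cv`
exactly and `residual_cv = 0` reproduces the model curve bit-for-bit.
Censoring applies after noise: values strictly below the LLOQ are flagged
`blq` and their numeric value removed, forcing the analysis layer to own the
imputation policy. A value exactly at the LLOQ is quantifiable.

One root seed drives everything; each subject consumes a substream seeded
deterministically from (root seed, group index, subject index), so editing
one group's size never perturbs another subject's draws, and the whole study
is byte-reproducible.

### The metabolite and the microsome module

The in-vivo metabolite follows the linear cascade depot → parent →
metabolite with first-order rates, implemented by its three-exponential
closed form (validated in the tests against independent ODE integration to
relative error < 10⁻⁶). Its Tmax necessarily lags the parent's.

The in-vitro module models microsome assays as two-step first-order
kinetics: parent depletion at `k_dep`, a formation branch `k_form ≤ k_dep`,
and onward metabolite clearance at `k_out` (the `k_out = k_dep` limiting form
is handled explicitly). The three species presets reproduce the qualitative
contrasts seen in primate liver-microsome comparisons — marmoset and macaque
deplete buprenorphine essentially completely by 15 min while human microsomes
leave measurable parent at 60 min; macaques clear the formed norbuprenorphine
to near zero by 45–60 min while the marmoset plateau persists. The presets
are qualitative anchors, not fitted constants.

## The noncompartmental analysis

### Integration

AUC uses the linear-up/log-down trapezoidal rule: rising, flat or
zero-bounded segments get the arithmetic trapezoid; declining positive
segments get the exact integral of the exponential interpolant. AUMC uses
the matching conventions: the exact integral of `t·C(t)` under the
exponential interpolant on log-down segments, and the moment trapezoid
`(t₁c₁ + t₂c₂)/2·Δt` — i.e. linear interpolation of the moment curve itself —
on linear segments. A `(0, 0)` anchor is prepended for extravascular dosing
when the first sample is post-dose.

BLQ policy: censored values before the first quantifiable sample count as
zero (drug genuinely near-absent), embedded and trailing censored values are
excluded from both integration and the terminal fit. The simulated studies
rarely censor mid-profile, but the policy is exercised directly in the tests.

### Terminal slope selection

No universal rule exists for choosing λz points; the de-facto standard of
the commercial NCA tools is adopted: candidate windows are the suffixes of
the quantifiable points strictly after Tmax (Cmax excluded), with at least 3
points; ordinary least squares of log-concentration on time; the window with
the best adjusted R² wins, and among windows within 10⁻⁴ of the best the one
with more points is preferred; a negative slope is required. When no window
qualifies, λz and everything downstream (t½, AUC₀₋∞, CL/F, MRT₀₋∞,
extrapolated threshold duration) are reported absent with a machine-readable
flag — at seven samples and 15% residual noise this genuinely happens, and
hiding it would misrepresent the design.

AUC₀₋∞ uses the *observed* Clast by default (the common commercial default);
a regression-predicted Clast is available via
`nca_options(clast_mode = "predicted")`. Extrapolated fractions above 20%
are flagged as a quality warning — at 72 h and t½ near 30 h some profiles
exceed it by construction, so it is never a hard failure.

Ties in Cmax resolve to the earliest time. The reported rate constant is
dimensionally 1/h (reports that print λz in "L/h" are a units slip: the
half-life relation t½ = ln 2/λz requires an inverse time).

### Threshold timing

Onset is the first *sampled* time at or above the threshold — never
interpolated before the first sample, mirroring how such studies report
"above threshold within 15 min". Downward crossings between samples are
log-linearly interpolated; a curve still above threshold at Tlast is either
extrapolated through the terminal fit (`tlast + ln(Clast/θ)/λz`, flagged
extrapolated) or, without a fit, censored at the end of observation with
duration `tlast − onset`. The group-level report computes both figures from
each group's mean curve, using the mean curve's own terminal fit (recorded in
`fit_source`); transient dips between onset and the final crossing are not
subtracted.

## Group statistics

Mean curves average quantifiable values per time point (zero-imputation
available by option) and report per-point n. Summaries use the n−1 sample
SD; a parameter's n counts only subjects for which it was estimable.

The Mann–Whitney test is exact by default: at these group sizes (3–8 per
group) all `choose(n₁+n₂, n₁)` assignments are enumerated, conditioning on
the observed values, with mid-ranks for ties; the two-sided p-value is
`P(|U − n₁n₂/2| ≥ |U_obs − n₁n₂/2|)` under that permutation distribution,
which handles tied and unbalanced samples without a symmetry assumption.
Beyond a combined n of 20 the tie-corrected, continuity-corrected normal
approximation is used and tagged as such. Bonferroni family size is always an
explicit argument: which comparisons form a family is a study-design fact
that cannot be inferred from the data; the shipped configuration uses a
family of 1 (plain Mann–Whitney), matching how PK parameters are typically
compared in these studies.

The dose-trend report (strict ordering of group-mean Cmax/AUC across
extended-release doses, log-log slope) is descriptive only.

## Numerical conventions and verification sizes

Units are fixed internally — hours, ng/mL (≡ µg/L), mg/kg, L/h/kg — so unit
conversion happens only at the dose boundary (mg → µg, exact). The test
suite verifies: segment formulas against adaptive quadrature of the declared
interpolants (1 000 random segments, relative error < 10⁻⁹); mass balance
`AUC₀₋∞·CL/F = dose` and terminal-slope recovery on noise-free dense grids
(0.02 h steps through the absorption phase, then 0.5 h steps out to 960 h,
about 45 terminal half-lives — long enough that the best-window search is
dominated by pure terminal phase); metabolite and microsome closed forms
against independent ODE integration; parameter recovery on 500 simulated
studies at the sparse design (median |relative bias| of CL/F under 10% and of
t½ under 15%, improving monotonically as residual error vanishes); exactness
of the Mann–Whitney p against brute-force enumeration, and its conservatism
under the null at n = 8 vs 8.

## Limitations

The simulator emulates the *statistical* structure of depot studies —
sparse schedules, log-normal variability, proportional error, censoring,
dose groups — not marmoset physiology: no protein binding, no body-weight
allometry, no enzyme-level metabolism, no pharmacodynamics. Passing
recovery tests therefore says the NCA is correct *given* data of this
structure; it cannot validate the mechanistic defaults against real animals.
Sparse 72 h designs intrinsically bias half-life estimation when absorption
is still ongoing at 24 h (quantified, not hidden, by the recovery tests),
and the terminal fit fails outright for subjects whose noisy Tmax lands at
24 h or later — the summaries report those subjects as missing rather than
imputing. The exact test is conservative at these sample sizes; with n = 3
per group only large effects are detectable, which is a property of the
design, not of the implementation.
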