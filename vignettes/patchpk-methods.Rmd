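---
title: "Methods: transdermal NCA, dose proportionality, and BLQ-aware tissue comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transdermal NCA, dose proportionality, and BLQ-aware tissue comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchpk)
```

`patchpk` analyses single-application transdermal patch studies of the
kind used to characterise a topical NSAID: a dose-escalation plasma
pharmacokinetic study in healthy volunteers (patch worn 24 h, rich
sampling out to 71 h), and a two-group deep-tissue study in patients
(patch worn 12 h, a single tissue/fluid/plasma sample at removal). This
vignette documents the models, the numerical decisions, and what the
bundled simulator does and does not emulate.

## Noncompartmental analysis

Each subject contributes one concentration–time profile. NCA makes no
mechanistic assumption beyond a log-linear terminal phase:

* **Cmax, tmax** are the maximum quantifiable observation and its
  sampled time — no interpolation. Ties go to the earliest time, a
  deterministic convention that matters only for flat, noise-free
  profiles.
* **λz** is minus the OLS slope of ln C versus t over the terminal
  window, and t½ = ln 2 / λz.
* **AUC0–t** is the linear trapezoid over quantifiable points up to the
  last quantifiable time t. A linear-up/log-down variant
  (`auc_method = "linlog"`) is available but the plain linear rule is
  the default, matching common practice when profiles are sustained
  rather than sharply peaked.
* **AUC0–∞** adds the tail Ct/λz, where Ct is the last quantifiable
  concentration. The extrapolated fraction is reported, with a warning
  (reporting aid, not a rejection rule) above 20 %.

### Terminal-window selection

Published analyses often say only "log-linear regression of the
terminal phase", leaving the point selection open. The package default
is the widely used automated best-fit rule: among contiguous suffixes of
the quantifiable points strictly after tmax (tmax itself excluded,
minimum 3 points), take the window maximising the adjusted R² of the
log-linear fit. It is reproducible, matches what most NCA software does
by default, and a manual `window =` override is provided for profiles
where a pharmacokineticist would choose differently. Profiles with fewer
than 3 eligible points, or whose best window has a non-negative slope,
get `NA` for λz and its dependents and are flagged rather than failed —
in a dose-escalation study the lowest dose routinely loses its tail to
the LLOQ.

### BLQ rules inside a profile

Below-LLOQ (BLQ) observations carry a flag and an undefined value; the
I/O layer never imputes. For NCA:

* a leading BLQ segment contributes through a zero anchor at time 0
  (before the patch there is genuinely no drug);
* interior BLQ points are dropped from the trapezoid nodes;
* trailing BLQ points truncate the profile — the last quantifiable point
  defines t and Ct.

These are the conventional rules; they are deliberately asymmetric with
the tissue-study imputation below, which serves a different purpose. One
edge case: a quantifiable concentration must be ≥ LLOQ, except that an
exact zero is accepted at any time and treated as a true zero (a
pre-dose baseline anchor), so that explicit `(0 h, 0)` rows and the
implicit anchor behave identically. AUC needs at least two nodes: two
quantifiable points, or one quantifiable point preceded by a BLQ record
(the anchor then supplies the second node).

## Patch mass balance

The percutaneous absorption ratio is (A − B)/A × 100 from the labeled
content A and the residual content B of the worn patch (both mg).
B > A or A ≤ 0 is an input error and is rejected, never clamped: a
residual exceeding the label indicates an assay or data problem that
silent clamping would hide.

## Dose proportionality

The power model ln y = α + β ln(dose) is fit by OLS to subject-level
(dose, value) pairs pooled within a dose range; the 95 % CI for β uses
the t distribution with n − 2 degrees of freedom, and proportionality is
declared when the CI contains 1. This is the simplest model consistent
with reporting a single coefficient and CI per range: no random subject
effect is needed because each subject contributes one observation per
parameter (single application), and natural logs are used throughout
(the base cancels in β; rescaling the dose unit shifts only α). Dose
ranges are configuration, defaulting to 2–20 mg (patch content varied),
20–60 mg (patch count varied) and 2–60 mg. The default ranges overlap at
20 mg by design, mirroring how escalation studies partition "content"
and "area" effects; the 20 mg observations legitimately enter both
fits. Because a subject-level refit of a published table cannot
reproduce printed coefficients exactly without the raw data, the
package treats printed coefficients as a plausibility check, not a
target; the tests instead verify exact recovery on constructed power
laws and calibrated coverage on simulated trials.

A perfect power law has zero residual variance; the CI then degenerates
to a point at β rather than propagating `NaN`.

`proportional_interpolation()` linearly interpolates a parameter between
two dose means — the standard way to quote an expected exposure at an
untested intermediate dose once proportionality holds — and
`exposure_ratio()` forms reference/test quotients, optionally rounded to
integers for "approximately k-fold" statements.

## Two-group tissue comparison

The deep-tissue study compares a test and a reference formulation in
small parallel groups (defaults n = 10 vs 9) across synovial tissue,
synovial fluid, plasma, and the absorption ratio.

* **Imputation**: BLQ values are set to the LLOQ (5.0 ng/g for synovial
  tissue; 0.500 ng/mL for fluid and plasma). When one arm is mostly
  censored this biases its mean *upward*, which is conservative for the
  hypothesis that the other arm is higher. The property
  `mean(zero-imputed) ≤ mean(LLOQ-imputed) ≤ mean(min-imputed)` is
  enforced by tests.
* **Summaries**: arithmetic mean, sample SD (n − 1), and the Student-t
  CI mean ± t(0.975, n−1)·sd/√n on the untransformed scale — this is
  the form that reproduces published absorption-ratio CIs exactly. The
  CI is suppressed whenever a group contains imputed values, since an
  interval centred on an imputation artefact would be misleading.
* **Welch's t test**: t = (m₁ − m₂)/√(s₁²/n₁ + s₂²/n₂) with
  Welch–Satterthwaite df — chosen because the two formulations produce
  grossly different variances. The test is computable from raw data or
  from (n, mean, sd) summaries; the two paths are algebraically
  identical, and the raw path is cross-checked against `stats::t.test`
  in the test suite. With equal n and equal sample variances it reduces
  to the pooled t. Both-variances-zero is an error (the statistic is
  undefined), while two identical overlapping samples give t = 0,
  p = 1.
* **Reporting**: p-values print to three decimals with a `<0.001`
  floor; fold-ratios of means to one decimal; means ± SD to three
  significant figures. Internal computation is always full precision.
* `sfp_from_racemate()` halves a racemic flurbiprofen measurement to
  estimate the S-enantiomer, justified by the near-unity S/R exposure
  ratio after oral dosing and the absence of chiral inversion; it is a
  reporting convenience, not a pharmacological model.

## The synthetic trial generator

The generator exists so that every stage has an executable ground truth.

**Kinetic form.** During wear, drug enters at the constant rate
k₀ = f_abs·dose/T (zero-order input) into a one-compartment model with
elimination rate ke and apparent volume V:

C(t) = k₀/(ke·V)·(1 − e^(−ke·t)) for t ≤ T, then C(T)·e^(−ke·(t−T)).

This is the simplest model consistent with the two qualitative features
of a tape-type plaster: a sustained, slowly rising plasma level during
wear (peak at patch removal) and mono-exponential decline afterwards. It
is a documented stand-in, not a claim about the product — the observed
spread of tmax in real data (10–18 h under 24-h wear) is compatible with
several input models, and first-order or diffusion-limited input would
change the approach to plateau without affecting what the tests use the
generator for.

**Defaults and their rationale** (all overridable in
`transdermal_params()`):

| parameter | default | why |
|---|---|---|
| ke | ln 2 / 8 h⁻¹ | 8-h terminal half-life, the centre of reported 7.6–8.4 h |
| v_f | 12.15 L | calibrated so the noiseless 20-mg 24-h plateau is ≈ 444 ng/mL; consistent with the small distribution volume of a highly protein-bound NSAID |
| f_abs | per-dose: 0.612/0.680/0.722/0.641/0.575/0.514 at 2/5/10/20/40/60 mg | matches observed mass-balance absorption means; absorption falls off at the doses achieved by stacking patches |
| between-subject CV | 25 % on ke, V, f_abs (lognormal) | typical magnitude for PK parameters in small healthy-volunteer studies |
| residual CV | 10 % (proportional lognormal) | typical bioanalytical + within-subject noise |
| LLOQ | 2 ng/mL (plasma study) | lower end of the validated assay range |
| schedule | 2, 4, 6, 8, 10, 12, 14, 24, 28, 32, 36, 47, 71 h; T = 24 h | the escalation-study design; the pre-application baseline is parsed but carries no drug and is ignored by NCA |

Passing a **scalar** `f_abs` gives an exactly dose-proportional truth
(mean Cmax ∝ dose, true β = 1); the per-dose default instead reproduces
the realistic mild sub-proportionality of mass-balance data. Simulation
studies that need a known β = 1 (CI coverage) therefore use the scalar
form, as do the acceptance checks; the per-dose calibration is the
default because it is what the study conditions looked like. The
absorbed fraction is capped at 0.995 after the lognormal draw (a
fraction cannot exceed 1); at the default CV this truncates ~3 % of
draws and shifts the mean by well under 1 %.

Patch records are generated jointly: residual content
B = A·(1 − f)·e^ε with a 2 % lognormal assay error ε, capped at A, so
mass balance and plasma exposure are consistent subject by subject.

**Tissue study.** Per-subject values are lognormal with moments matched
to per-group targets (meanlog = ln m − σ²/2, σ² = ln(1 + (s/m)²); any
positive mean/SD pair is attainable, so only non-positive means are
rejected). Targets default to the observed group summaries, with one
exception: the reference-group synovial tissue target is mean 3.0, SD
2.5 ng/g — *below* the 5 ng/g LLOQ — because the observed
5.70 ± 2.10 ng/g is itself an LLOQ-imputed summary (8 of 9 censored),
not the underlying truth. Under this target ~86 % of draws are censored,
reproducing the mostly-BLQ pattern; the simulated BLQ fraction is tested
against the analytic lognormal tail probability.

**What the generator does not emulate**: actual-versus-nominal sampling
times, dropout or missing samples, assay batch effects, correlated
between-subject parameters, skin-site or formulation covariates, and any
within-subject kinetics more complex than one compartment. Passing tests
therefore demonstrate that the *estimators* are correct and calibrated
under a clean data-generating process matching the study design — not
that real data meet these assumptions.

## Reproducibility and problem sizes

Seeds are explicit arguments everywhere (`simulate_*`, `run_pipeline`
via its config); the same seed yields byte-identical datasets and
reports, and no function touches the global RNG without one. The
simulation studies in the tests and acceptance script use: 500 replicate
trials of 41 subjects for power-model CI coverage (Monte-Carlo SE ≈ 1 %
at 95 % coverage), 2000 null replicates at n = 10 vs 9 for the Welch
type-I error (SE ≈ 0.5 %), 2000 replicates for CI coverage of the group
mean, and 500 subjects for median-λz recovery — sizes chosen so the
Monte-Carlo error is well inside each assertion's tolerance.

## Known limitations

* No compartmental fitting, steady-state/superposition prediction, or
  repeated-application accumulation — single application only.
* No nonparametric alternatives to Welch's test and no multiplicity
  adjustment; the tissue study is analysed exactly as designed (one
  planned comparison per matrix).
* The power model is fixed-effects OLS; a mixed-effects power model
  would be needed for crossover or repeated-measures designs.
* Units are fixed (hours; ng/mL for fluids, ng/g for tissue; mg for
  doses and patch content); there is no unit inference or conversion.
* I/O covers a configurable delimited-text dialect only — no
  CDISC/SDTM or NONMEM dataset support.
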