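---
title: "Measuring fluctuating asymmetry from replicated bilateral measurements"
author: "flucasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fluctuating asymmetry from replicated bilateral measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucasym)
```

## The problem

Fluctuating asymmetry (FA) — small, random, non-directional departures
from perfect bilateral symmetry — is a widely used proxy for
developmental instability: the failure of a developing organism to
buffer its phenotype against genetic and environmental noise. Dental
enamel does not remodel after formation, so asymmetry between antimeric
teeth (left/right counterparts) preserves a permanent record of
conditions during the developmental window of each tooth. This package
implements the full measurement-to-inference chain for such data, built
around a study of postcanine dental asymmetry in wild Nigerian olive
baboons (*Papio anubis*): replicated left/right crown measurements in,
group-level variance tests on ME-corrected FA indices out.

The central statistical difficulty is that FA in well-canalized traits
is tiny — often the same order as caliper measurement error (ME) — and
is easily confounded by other forms of asymmetry. The package therefore
separates four concerns:

1. **partitioning**: a sides-by-individuals ANOVA that splits
   directional asymmetry, individual size variation, nondirectional
   asymmetry, and replicate measurement error into separate strata;
2. **screening**: tests for directional asymmetry (DA), antisymmetry
   (AS), trait-size dependency and outliers, with explicit
   variable-elimination rules;
3. **indexing**: the FA1/FA4a/FA10a index family and the ME3
   repeatability descriptor;
4. **group inference**: Levene-type tests of FA-index variance across
   groups of trait variables.

## The sides-by-individuals model

For one trait variable (a tooth, a metric, within a sex stratum), the
data are a balanced J × 2 × M array: J individuals, two sides, M
replicate measurements per side (`trait_matrix`). The two-way mixed
model with sides fixed and individuals random decomposes the total sum
of squares into four strata:

| stratum            | df       | interpretation                     |
|--------------------|----------|------------------------------------|
| sides              | 1        | directional asymmetry              |
| individuals        | J − 1    | between-individual size variation  |
| sides × individuals| J − 1    | nondirectional asymmetry (FA + AS) |
| error (replicates) | 2J(M − 1)| measurement error                  |

`fit_sides_anova()` computes the balanced closed-form sums;
method-of-moments estimators then give the two variance components
(`variance_components()`):

- σ²ᵢ = (MS_interaction − MS_error) / M, the nondirectional
  between-sides component;
- σ²ₘ = MS_error, the single-measurement error variance.

A negative raw σ²ᵢ (sampling noise when FA is small relative to ME) is
clamped to zero and flagged, never propagated.

One convention matters and is easy to get wrong. Writing the signed
asymmetry of individual *i* as dᵢ = Rᵢ − Lᵢ (side means; right minus
left throughout the package), the interaction stratum receives ±(dᵢ −
d̄)/2 in the two cells of individual *i*, so σ²ᵢ converges to
**var(d)/2**, not var(d). Consequently

- FA10a = 0.798·√(2σ²ᵢ) estimates 0.798·sd(d) with the ME contribution
  removed, where 0.798 = √(2/π) converts a normal SD into a mean
  absolute deviation;
- FA4a = 0.798·√(var dᵢ) estimates the same quantity but is inflated by
  2σ²ₘ/M, since replicate noise enters the observed side means;
- FA1 = mean|dᵢ| is the raw mean absolute asymmetry.

At zero ME the three indices agree (a property test asserts this); as
ME grows, FA4a and FA1 inflate while FA10a does not — the reason the
ME-corrected index is the one carried into hypothesis testing.

ME3 = 100·σ²ₘ/(σ²ᵢ + σ²ₘ) expresses measurement error as a percentage
of the total nondirectional between-sides variance; it is unit-free and
comparable across traits. Repeatability is its complement,
1 − ME3/100. When σ²ᵢ + σ²ₘ = 0 (degenerate noise-free symmetric
input) ME3 is undefined and returned as `NA` with a warning. The
replicate-subset scan (`replicate_scan()`) recomputes per-variable ME3
for each contiguous subset of trials and reports both a
variance-weighted pooled percentage, 100·Σσ²ₘ/Σ(σ²ᵢ + σ²ₘ), and the
mean/median/min/max/range of the per-variable values — two aggregations
that can differ substantially when ME varies across variables, so both
are always emitted.

## Screening and elimination

All screens operate on the per-individual side differences dᵢ
(`screen_trait()`), with α = 0.05 by default:

- **Directional asymmetry.** The study criterion is a significant skew
  of the dᵢ distribution (D'Agostino standardized test); the
  conventional criterion is a mean of dᵢ shifted from zero (one-sample
  t). Both are always computed; the flag rule is configurable
  (`da_rule`): `"either"` (default), `"skew"`, or `"t"`. The default is
  deliberately inclusive because the two criteria detect different
  departures — a side-consistent offset moves the mean without skewing,
  and a one-tailed wear process skews without necessarily shifting the
  mean far.
- **Antisymmetry.** Present-in-all, random-side asymmetry produces a
  broad-peaked or bimodal dᵢ distribution; the flag requires a
  significant one-sided Anscombe–Glynn platykurtosis test together with
  negative excess kurtosis. The cube-root normalization of that test
  leaves its domain for extreme platykurtosis (its denominator crosses
  zero); the implementation returns z = −∞ there, i.e. overwhelming
  evidence, where a naive transcription produces a spurious large
  positive statistic.
- **Trait-size dependency.** Spearman rank correlation of |dᵢ| with
  individual trait size sᵢ = (Rᵢ + Lᵢ)/2, robust to outliers and to
  the monotone-but-nonlinear dependencies a size-scaling mechanism
  produces. Ties are handled by the normal approximation.
- **Outliers.** Iterative two-sided Grubbs flagging at α per step.
  Flagged individuals are reported, never silently removed: exclusion
  is the caller's decision.

Moment tests need J ≥ 8; below that (or with constant dᵢ) the trait is
reported not-evaluable, verdict clean-with-warning. The verdict
priority is DA > AS > size-dependent, and `apply_elimination()` turns
flags into a ledger (variable, reason) plus a retained roster. On the
study's roster the published pattern — four mandibular M1/M2 length
variables eliminated for DA, male maxillary P3 length for size
dependency — leaves 9 female breadth, 7 female length, 9 male breadth
and 6 male length variables.

When screening a whole roster (36 candidate variables), the workflow
scripts use a much stricter per-screen level (α = 1e-4) so that the
family-wise probability of any false flag stays negligible; with
planted confounders of realistic strength (0.3 mm DA offset; size
scaling exponent 8) detection power remains ≈ 1. Calibration tests
verify both sides of this: under the null every screen's false-positive
rate at α = 0.05 sits within binomial error of 5% (2000 simulated
traits at J = 200), and planted DA at 2σ and AS at 3σ are detected
with power ≥ 0.95.

## Group-level inference

Because an FA index is itself a variance-like quantity, comparing FA
across groups is a homogeneity-of-variance question. `levene_test()`
implements the Levene/Brown–Forsythe statistic — a one-way ANOVA F on
absolute deviations of each value from its group center — with both
centerings: median (Brown–Forsythe, default, matching the default of
the standard R implementation) and mean (classical Levene). Tests run
on the index values themselves, one value per trait variable, exactly
as the published degrees of freedom imply (e.g. 1/29 for the sex
contrast over 31 values); no multiple-testing correction is applied, to
match the original presentation (users can p.adjust downstream).

`run_hypothesis_suite()` emits the nine models of the study's two
results tables in order: the four data-exploration factors (tooth code,
tooth class, arcade, metric), the sex contrast, and the two
life-history contrasts — first molar (developmental window overlapping
weaning) and third molar (overlapping reproductive maturation) against
all other teeth, each alone and crossed with sex. The molar contrasts
pool arcades and metrics, reflecting the near-synchronous eruption of
upper and lower molars in baboons.

**Reproduction policy.** The bundled published index table carries
values printed at two decimals. Recomputing the nine tests from those
rounded inputs, mean centering reproduces the full published
significance pattern and all degrees of freedom; median centering does
not. The mean-centred table is therefore the headline reproduction.
The F statistics of the well-separated contrasts (sex and the two
interaction models) land within ~13% of the published values; the
small-F models (class, arcade, the plain molar contrasts) are
intrinsically sensitive to input rounding — absolute deviations of
values spanning only a few hundredths of a millimetre change by whole
rounding steps — so their reproduced F values should be read as
order-of-magnitude checks, not exact matches. This is a limitation of
reproducing from printed values, not of the test implementation, which
is verified against an independent reference implementation to 1e-10.

## The synthetic generator

`synthetic_config()` / `simulate_dataset()` draw one trait's records
from an explicit generative model: individual size Tᵢ ~ N(μ, τ²); a
signed asymmetry Aᵢ = DA offset + FAᵢ + ASᵢ with FAᵢ ~ N(0, σ_fa²) and
ASᵢ = ±δ (fair-coin side) with mixture probability p; true sides
Tᵢ ± Aᵢ/2; independent N(0, σ_me²) error on every replicate
measurement (optionally per-trial σ_me, for the ME scan's planted
signal); whole (individual, side) cells dropped at a missingness rate.
`simulate_study()` stamps a roster of such configs with deterministic
per-trait substreams of one global seed, so any subset of traits is
reproducible independently of roster order.

Defaults emulate the baboon study's conditions: J = 25 per trait
(published per-variable n runs 14–35), M = 10 replicate trials, crown
dimensions ~10 ± 0.8 mm, σ_fa = 0.035 mm (FA10a in the published
0.01–0.10 mm range), σ_me = 0.01 mm (per-variable ME3 near 8%). Under
this model var(dᵢ) = σ_fa² + p·δ² + 2σ_me²/M, mean(dᵢ) = DA offset,
and the planted interaction component is σ_fa²/2 — closed forms the
recovery tests assert at J = 5000 within 5%. Antisymmetry is modelled
as the simplest mechanism producing the platykurtic/bimodal signature
(a two-point admixture); trait-size dependency scales the FA deviation
SD by (Tᵢ/μ)^γ.

What the generator does **not** emulate: occlusal/interstitial wear
(the likely biological source of the study's DA), spatially or
temporally correlated measurement error, caliper resolution
quantization, eruption-timing differences, or correlated missingness
across a jaw. Passing recovery and calibration tests therefore show
that the estimators are correct under the stated model, not that real
dental data satisfy it — which is precisely why the screening battery
exists.

## Numerical and design choices

- Balanced designs only: incompleteness is resolved upstream by
  complete-case subsetting per trait (`build_trait_matrices()`), never
  by imputation. An individual missing any required cell for a trait is
  excluded from that trait alone, matching a study design in which
  partial dentitions are common.
- Side difference is right minus left everywhere; FA indices are
  invariant to measurement shift and scale linearly (property-tested).
- Negative variance-component estimates clamp to zero with a flag.
- Grubbs critical values use the exact t-based formula; flagging is
  location/scale-invariant.
- Test problem sizes: the ANOVA oracle check runs 100 random small
  designs (J ≤ 6, M ≤ 4) against a brute-force summation oracle at
  1e-10; the recovery grid crosses σ_fa ∈ {0.02, 0.04, 0.08} ×
  σ_me ∈ {0.01, 0.04} × J ∈ {50, 200} × M ∈ {2, 10} with 200
  replicates per cell, asserting ≤ 10% median relative bias for FA10a
  and ≤ 5-point error for ME3 wherever σ²ᵢ ≥ σ²ₘ/M (outside that
  region the interaction contrast is ME-dominated and no estimator of
  this form is informative).
- The package is organised as an analysis workflow: the numbered
  scripts under `analysis/` are thin narrative drivers over the
  exported functions, writing their tables under `results/`; they are
  the package's command-line surface.

## Limitations

Reproduction of the original measurement-level quantities (per-variable
ME3 percentages, the FA10a values themselves) requires the study's raw
measurement repository, which is external; the package reproduces the
group-level inference from the published index table and validates the
measurement-level machinery by simulation instead. The Levene tests
treat index values as exchangeable observations, ignoring that each
carries its own estimation error and sample size; that matches the
original analysis but a weighted or individual-level approach could be
more efficient. The DA screen's two criteria can disagree; both are
reported precisely so that the analyst can see why a variable was
eliminated.
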