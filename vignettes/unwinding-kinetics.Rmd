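---
title: "Models and methods for replication-fork unwinding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for replication-fork unwinding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindr)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, and the numerical and design choices that a
user fitting real stopped-flow or 2-aminopurine (2-AP) data should know
about.

## The n-step trace model

A stopped-flow unwinding trace reports, through a fluorophore/quencher
pair, the fraction of fork molecules whose duplex has fully separated.
Unwinding of an `L`-bp duplex is modelled as `n` sequential irreversible
steps, each of size `s = L/n` bp and first-order rate constant `k` (s⁻¹).
The time to complete all `n` steps is then Erlang-distributed, and the
expected unwound fraction is the Erlang CDF

> F(t) = P(Γ(n, k) ≤ t),

the regularized lower incomplete gamma function of order `n` at `kt`
(`erlang_fraction_unwound()`). The observable is
`baseline + amplitude · F(t)`. Two consequences drive the fitting:

- the mean completion time is `n/k`, so the macroscopic average unwinding
  rate is `s·k = L·k/n` (`average_unwinding_rate()`);
- for `n > 1` the trace has a presteady-state lag (at one tenth of the
  mean time the signal is far below 1% of the amplitude for `n ≥ 10`),
  and the lag sharpens as `n` grows. A shorter duplex at the same
  per-step rate gives a shorter lag.

Assumptions worth stating: all steps share one rate constant (kinetic
heterogeneity between steps is not identifiable from a single trace);
steps are irreversible on the observation timescale; any pausing is
absorbed into the average rate. The model is agnostic about what one
"step" is physically — `n` need not equal `L`, and the fitted step size
`s = L/n` is the operational answer to that question.

### Fitting and the n profile

`fit_nstep()` exploits the model's structure: for fixed `(n, k)` the
baseline and amplitude enter linearly and are solved exactly by linear
least squares, so the only genuine nonlinear dimension is `k`, optimized
on a log scale by golden-section/Brent search around the deterministic
initializer `k₀ = n / t₁/₂` (time at half-amplitude). `n` is an integer
and is either fixed or profiled over a grid (default 2–80); the winner is
the minimal-SSE `n`, with ties within 0.1% of the minimum resolved toward
smaller `n` — parsimony, and a guard against the flat SSE valleys that
neighbouring `n` produce at realistic noise. We deliberately kept `n`
integer rather than introducing a continuous gamma shape parameter: the
sequential-step interpretation is the point of the model, and the profile
also exposes how weakly `n` is determined, which a continuous estimate
would hide.

Degenerate inputs are flagged, never silently fitted: a trace whose
fitted amplitude is within two standard errors of zero returns status
`"degenerate"`; a rate estimate pinned at the search boundary returns
`"boundary"`. An optional plateau truncation (first time the smoothed
trace exceeds 98% of its maximum) restricts the window when a slow
post-plateau fluorescence dip is present; the dip is a fluorophore
artifact, not mechanism, so the default is to fit the full trace.

`estimate_lag()` is a model-free diagnostic: the time-axis intercept of
the tangent at the maximal-slope point of a smoothing-spline fit. It is
reported alongside fits, not used by them.

## Steady-state rate laws

All mechanistic rate laws are rapid-equilibrium occupancy models: the
enzyme distributes among its states according to equilibrium constants,
and the rate is `kcat` times the occupancy of the catalytically competent
state. This treatment matches how the constants are used — dissociation
constants are fixed at independently measured values and only the
capture equilibria and `kcat` float — and it keeps every law exactly
hyperbolic in nucleotide concentration, which is what the data show. A
full steady-state (finite-exchange-rate) treatment would add parameters
the titrations cannot constrain, and is deliberately out of scope.

**Ordered polymerase scheme** (`ordered_rate()`): base capture
(Pol ⇌ Pol·base, equilibrium `K1`, dimensionless), then dNTP binding
(`Kd_nt`, default 10 μM — the polymerase's dNTP constant on
primer-template DNA), then incorporation (`kcat`). The law is

> rate = kcat · c / (Kd_nt·(1 + 1/K1) + c),

so base capture acts like a competitive inhibitor of its own substrate:
apparent Km = `Kd_nt(1 + 1/K1)` grows as capture gets harder, while the
saturating rate is `kcat` regardless of `K1`. That separation — Km moves,
Vmax does not — is the testable signature of the ordered scheme.

**Helicase base-capture schemes** (`capture_model_rate()`): with
`x = c/Kd_t` (`Kd_t` default 90 μM, the dTTP constant during
single-stranded translocation) and `kcat` default 130 nt/s (the
translocation rate on single-stranded DNA):

- variant A (capture then bind): rate = kcat·K1·x / (1 + K1 + K1·x).
  Saturating rate `kcat` independent of `K1` — structurally unable to
  produce a GC-dependent Vmax, which is why it fails on unwinding data;
- variant B (bind then capture): rate = kcat·K2·x / (1 + x + K2·x), with
  Vmax = kcat·K2/(1+K2) and apparent Km = Kd_t/(1+K2);
- variant C (random order): rate = kcat·K2·x / (1 + K1 + x + K2·x), with
  Vmax = kcat·K2/(1+K2) and apparent Km = Kd_t(1+K1)/(1+K2). The fourth
  edge of the thermodynamic cycle (dTTP binding to the captured state) is
  always computed from detailed balance, `Kd' = K1·Kd_t/K2`, never a free
  parameter. Variant C reduces exactly to B at `K1 = 0`.

Which physical order "variant A" denotes is a convention (capture-first
here), recorded in `run_config()`.

One known tension: in the rapid-equilibrium variant C the apparent Km is
`Kd_t(1+K1)/(1+K2)`, so a roughly constant-to-falling Km across GC levels
constrains `(1+K1)/(1+K2)` near or below 1 even as both equilibria fall.
Fits should be read with that coupling in mind; `fit_capture_models()`
reports per-dataset standard errors and boundary flags rather than
forcing any Km behaviour.

Degenerate boundaries (`K1 = 0` or `K2 = 0`) return zero rates with a
`degenerate` attribute instead of raising, so global fits can traverse
them.

### The occupancy oracle

`steady_state_rate_oracle()` evaluates any scheme expressed as a
state/edge graph (`kinetic_scheme()`) by brute force: occupancies are
propagated over a spanning tree, every remaining edge is checked for
detailed balance to within 1e-12, and the rate is `kcat` times the
normalized occupancy of the catalytic state. It shares no algebra with
the closed forms, which is the point: every law above is required (in the
test suite) to agree with it to 1e-10 relative over random parameter
draws.

## Fitting and model discrimination

`fit_hyperbola()`, `fit_ordered_global()` and `fit_capture_models()` all
use Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with
equilibrium constants and `kcat` log-parameterized — positivity by
construction, no penalty terms — and cost tolerances of 1e-12. Weights
are inverse-variance when per-point errors are available. The global
ordered fit shares one `kcat` across datasets and gives each dataset its
own `K1`; fixed constants are echoed verbatim into results and reports,
never refitted.

Model ranking (`select_model()`) uses Gaussian-likelihood AIC,
`n·log(SSE/n) + 2(p+1)` with the error variance counted as a parameter.
Discrimination among variants A/B/C is traditionally done by eye on
overlaid fit curves; the AIC criterion with a ΔAIC ≥ 2
evidence cutoff is this package's quantitative replacement, chosen
because it is the standard weak-evidence threshold and because variant C
nests B, making a penalty-aware criterion mandatory. Fits on
non-identical data refuse to be ranked.

## 2-AP footprints and synergy

2-AP is an adenine analog whose fluorescence rises when its base pair
melts and the base unstacks; a single 2-AP at position N+k (k base pairs
downstream of the primer 3′ end N) reports melting at single-base
resolution. `correct_intensity()` applies the background correction
(buffer, and protein bound to an unlabeled fork); `fold_change()` forms
protein/DNA-only ratios with first-order error propagation;
`classify_response()` quantizes a fold into increase/none/decrease with
two gates — effect size (`δ`, default 0.2) and significance (`z`, default
2 propagated standard deviations). The canonical qualitative patterns
the package ships as generators are robust to `δ` anywhere in
[0.1, 0.3]; the defaults are conventions, exposed in `run_config()`,
because bar heights in published figures are not data.

`infer_footprint()` walks the reference fork's base pairs outward from
the junction and counts the maximal run called "increase", with one
attribution rule: an increase at an internally probed position is
credited to unstacking of the already-melted neighbour — not to melting
at that position — whenever the same absolute position probed *at the
junction* (a fork with a larger primer-end gap) shows no increase. If
that disambiguating construct is missing, the result says "ambiguous
attribution" rather than guessing. On the leading strand, any response
(increase or decrease) is contact evidence, and the contacted-bases count
is the contiguous span bounded by the outermost responding positions — a
silent probe flanked by responding ones sits inside the binding pocket,
held but not unstacked.

Synergy (`detect_synergy()`) is defined on excess-over-baseline folds
ΔF = fold − 1: the combined-enzyme excess must exceed the sum of the
single-enzyme excesses by more than `z` propagated standard deviations.
Summing raw folds would double-count the baseline; exact additivity is
not synergy. `max_synergy_gap()` applies the test at each
primer-end-to-junction gap and expects contiguity (cooperation across a
gap implies cooperation across smaller ones); violations are flagged
rather than truncated.

## The synthetic-data generators

The generators exist so every estimator can be exercised against known
truth, seeded and bit-reproducible, with no global RNG state touched:

- `simulate_trace()`: analytic mode adds i.i.d. Gaussian noise (default
  sd 2% of amplitude — typical stopped-flow scatter) to the Erlang curve;
  stochastic mode reports the unwound fraction of a finite ensemble whose
  first-passage times come from `gillespie_first_passage()`, the exact
  stochastic simulation of the linear chain (sum of `n` exponentials per
  molecule). 500 points over four mean-completion times by default.
- `simulate_titration()`: model rate × (1 + Gaussian(0, 3%)), truncated
  at zero, on 8 log-spaced concentrations (dTTP 25–2000 μM, dNTPs
  5–1000 μM — the regimes the titrations actually cover).
- `simulate_ap_panel()`: reference × fold × (1 + Gaussian noise) with a
  DNA-only row per construct; `ap_pattern_dnap()`,
  `ap_pattern_helicase()` and `ap_pattern_synergy()` encode the
  qualitative response patterns of the two enzymes (fold 1.6 for a clear
  increase, 1.4/3.2 for the additive/synergistic combined conditions) —
  values chosen to sit comfortably clear of the call thresholds at the
  default noise, since only the qualitative pattern is data.

What the generators do **not** emulate — and hence what passing tests do
not establish about real data: sequence-dependent stepping and pausing,
fluorophore photophysics beyond the optional post-plateau dip nuisance
term, SSB binding kinetics and two-phase traces, instrument dead time,
and correlated (non-i.i.d.) noise. Parameter-recovery results here bound
estimator error under the stated noise model only.

## Problem sizes and runtimes

The shipped test suite and acceptance script run at desk scale by
design: Gillespie/Erlang agreement uses 5,000-molecule ensembles
(Kolmogorov distance ≤ 0.02); trace-fit recovery uses 100 replicates of
250-point traces at 2% noise (average rate within 5% of truth in ≥95% of
replicates); model discrimination uses 100 replicates of three 8-point
titrations at 3% noise (variant C preferred with ΔAIC ≥ 2 over A in
≥90%). These sizes were chosen so each statistical claim is tested at the
power it needs and the whole suite stays in the order of a minute.

## Known limitations

- The n-step fit assumes homogeneous steps; real forks pause, and the
  fitted `n` soaks up dispersion, so `n` should be read as a shape
  parameter, not a literal step count.
- Rapid equilibrium is an approximation; if capture or binding exchange
  is slow relative to `kcat`, apparent constants conflate kinetics with
  thermodynamics.
- The footprint logic consumes qualitative calls; it is only as good as
  the classification thresholds, and panels lacking the disambiguating
  junction constructs return ambiguous rather than best-guess counts.
- No coupled helicase–polymerase mechanistic model is fitted; combined
  -enzyme titrations are analyzed with the same single-enzyme laws and
  the coupling is interpreted through the fitted constants.
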