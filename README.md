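# unwindr

Kinetic and fluorescence analysis of replication-fork DNA unwinding.

Replicative helicases and DNA polymerases (DNAPs) both have to open duplex
DNA at a replication fork, and stopped-flow fluorescence is the standard way
to watch them do it: a fluorophore/quencher pair reports strand separation,
and the trace shows a presteady-state lag followed by a rise. `unwindr`
provides the models and estimators used to turn such data — and steady-state
2-aminopurine (2-AP) fluorescence panels — into mechanistic numbers:

- **n-step trace model.** Unwinding of an L-bp duplex is modelled as *n*
  sequential irreversible steps of equal size *s* = L/*n* and rate constant
  *k*. The unwound fraction at time *t* is the Erlang(*n*, *k*)
  first-passage CDF, P(Γ(n, k) ≤ t), and the observable is
  baseline + amplitude · F(t). `fit_nstep()` estimates (*n*, *k*, baseline,
  amplitude) from a trace and reports the average unwinding rate *s·k*.
- **Hyperbolic kcat/Km extraction.** Average rates vs nucleotide
  concentration follow rate = *k*cat·c / (*K*m + c); `fit_hyperbola()` does
  weighted nonlinear least squares with under-determination flags.
- **Mechanistic rate laws and model discrimination.** Rapid-equilibrium
  occupancy models for the ordered polymerase scheme (base-capture *K*₁ →
  dNTP binding *K*d → incorporation *k*cat; apparent
  *K*m = *K*d(1 + 1/*K*₁)) and for three helicase base-capture/dTTP-binding
  schemes (A: capture-then-bind, B: bind-then-capture, C: random order with
  the fourth edge fixed by detailed balance). `fit_ordered_global()` shares
  *k*cat across GC-content series; `fit_capture_models()` +
  `select_model()` rank variants A/B/C by AIC.
- **2-AP footprinting.** `infer_footprint()` turns corrected 2-AP
  intensities into counts of melted base pairs and contacted template
  bases, with the junction/internal attribution rule for unstacking;
  `detect_synergy()` and `max_synergy_gap()` decide whether two enzymes
  melt the junction base pair synergistically and over what
  primer-end-to-junction gap.
- **Synthetic data and oracles.** Seeded generators for traces (analytic or
  Gillespie-simulated ensembles), titrations and 2-AP panels, plus a
  numeric steady-state occupancy oracle (`steady_state_rate_oracle()`) that
  validates every closed-form rate law.

## Worked example

Fit a simulated 40-bp unwinding trace and a two-GC-level titration series:

```r
library(unwindr)

p <- nstep_params(n_steps = 40, step_rate = 150, duplex_length = 40,
                  baseline = 0.05, amplitude = 1)
trace <- simulate_trace(p, noise_sd = 0.02, seed = 7)
fit_nstep(trace, duplex_length = 40, n_range = 10:80)
#> n-step model fit (converged)
#>   n = 40, step_rate = 150.21 s^-1, step size = 1 bp
#>   baseline = 0.052732, amplitude = 0.9971 (a.u.)
#>   average unwinding rate = 150.21 bp/s
#>   SSE = 0.1976 over 500 points
```

The fitted per-step rate (150.21 s⁻¹) recovers the generating 150 s⁻¹; with
a 1-bp step size the average unwinding rate is the same number in bp/s.

```r
datasets <- lapply(c(20, 65), function(gc) {
  K1 <- if (gc == 20) 1/3 else 1/26   # base capture is harder at high GC
  simulate_titration(ordered_params(K1, Kd_nt = 10, kcat = 160),
                     relative_noise = 0.03, seed = gc,
                     metadata = list(GC_percent = gc))
})
fit_ordered_global(datasets, Kd_nt = 10)
#> mechanism fit: ordered
#>   fixed constants: Kd_nt = 10
#>   shared kcat = 155.13 +/- 2.9
#>  dataset      K1    K1_se apparent_Km
#>     GC20 0.36130 0.018851       37.68
#>     GC65 0.03942 0.001193      263.70
#>   pooled SSE = 19.211, AIC = 10.93 (16 points)
```

The global fit holds the dNTP dissociation constant at 10 μM, floats one
*k*cat for all series, and returns a base-capture equilibrium per series:
K₁ falls from ≈0.36 to ≈0.04 as GC rises, which is exactly what pushes the
apparent dNTP *K*m from ≈40 μM to ≈270 μM while the saturating rate stays
put. For the helicase schemes, fitting all three variants to data generated
from the random-order model and ranking them:

```r
fits <- fit_capture_models(lapply(1:3, function(i)
  simulate_titration(capture_params(K1 = 0.5, K2 = 1, Kd_t = 90,
                                    kcat = 130, variant = "C"),
                     relative_noise = 0.03, seed = i)))
select_model(fits)
#>      model      aic delta_aic
#>  capture_C  -2.9595     0.000
#>  capture_B  57.8444    60.804
#>  capture_A 137.4756   140.435
#> winner: capture_C (threshold delta AIC >= 2)
```

And the 2-AP footprint of a polymerase-pattern panel:

```r
panel <- simulate_ap_panel(ap_pattern_dnap(noise = 0.02), seed = 1)
infer_footprint(panel, "+DNAP")
#> 2-AP footprint, condition +DNAP (ok)
#>   melted base pairs: 2
#>   contacted template bases (leading strand): 3
```

The increase at the internally probed third base pair is attributed to
unstacking of the melted second base pair (the junction-context probe of
the same position is silent), so the melted count stays at 2.

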