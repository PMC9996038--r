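# hergate

Quantitative analysis of hERG1 (Kv11.1) potassium-channel gating and its
modulation by activator compounds, for electrophysiologists working with
two-electrode voltage-clamp data from *Xenopus* oocytes (wild-type hERG1a,
split channels, N-/C-terminal deletions, the D540K mutant) and for anyone
who needs a tested, scriptable version of the standard analysis stack:

* **6-state equilibrium gating model** — four independent voltage-sensor
  transitions followed by a concerted opening step,
  `C0 ⇌ C1 ⇌ C2 ⇌ C3 ⇌ C4 ⇌ O`, with closing-direction constants
  `K(V) = K(0)·exp(−z₁FV/RT)` and `Ko(V) = Ko(0)·exp(−z₂FV/RT)` and the
  closed-form normalized conductance
  `g/gmax = [1 + Ko + 4KoK + 6KoK² + 4KoK³ + KoK⁴]⁻¹ = [1 + Ko(1+K)⁴]⁻¹`.
* **Q-matrix kinetic simulator** of arbitrary step voltage-clamp protocols,
  consistent with the equilibrium model by construction (matrix-exponential
  propagation, mean-field current, seeded noise).
* **Nonlinear least-squares fitting** of Boltzmann and double-Boltzmann G-V
  curves, the logistic (Hill) concentration-response
  `y = Amax + (Amin − Amax)/(1 + (c/EC50)^nH)`, 1-3 component exponential
  tail decays, and the 6-state model itself, with F-test exponential
  model-order selection.
* **Trace measurement operators** — peak and tail-peak extraction, G-V
  assembly from tail currents under both normalization conventions, per-sweep
  deactivation time-constant curves, and the tail-ratio statistic
  `I_tail-end/I_tail-peak` with its Boltzmann-fitted midpoint.
* **Seeded synthetic-data generators** for every dataset shape above,
  including a one-command synthetic study bundle, so the full pipeline is
  testable with no recordings.

## Worked example

```r
library(hergate)
ctx  <- thermo_context()                     # 22 °C
ctrl <- gating_params(K0 = 0.155, z1 = 1.71, Ko0 = 0.32, z2 = 0.73)

round(po_equilibrium(ctrl, c(-40, -20, 0, 20, 40), ctx), 3)
#> [1] 0.008 0.214 0.637 0.826 0.904
```

The open probability of this control split-channel parameter set rises from
essentially closed at −40 mV through 0.637 at 0 mV toward saturation.

```r
d <- gen_dose_response(hill_params(Amax = 4, Amin = 1, ec50_uM = 7.9, nH = 1.9),
                       concs_uM = c(1, 3, 5, 10, 20, 30),
                       noise = noise_spec(frac_span = 0.03, seed = 1), n = 5)
fit_hill(d)
#> <herg_fit:hill> converged (rss = 0.1624, n = 30)
#>   Amax       3.9652 +/- 0.0668
#>   Amin       1.0123 +/- 0.0442
#>   ec50_uM    7.7247 +/- 0.276
#>   nH         1.9577 +/- 0.13
```

A synthetic concentration-response for a 4-fold slowing of deactivation
(EC50 = 7.9 µM, nH = 1.9, 3%-of-span noise, 5 replicates) is refit: the
recovered EC50 of 7.72 µM is within 2.5% of the generating value.

```r
seg <- gen_tail_trace(exp_mixture(c(44, 1451), c(0.6, 0.4)),
                      dt_ms = 2, duration_ms = 8000,
                      noise = noise_spec(sd = 0.02, seed = 2))
sel <- select_exp_order(seg)
sel$order
#> [1] 2
coef(sel$fits[[sel$order]])
#> <exp_mixture> order 2: tau = [43.34, 1451] ms, A = [0.6058, 0.4012], C = 0.000662
```

A biexponential drug-modified tail (τf = 44 ms, τs = 1451 ms, 40% slow
amplitude) is correctly identified as order 2 by the extra-sum-of-squares
F-test, and both time constants and the amplitude split are recovered.

```r
r    <- rate_params(ctrl)
prot <- voltage_protocol(list(c(1000, 50), c(500, -100)),
                         sample_interval_ms = 0.5,
                         holding_mV = -70, holding_ms = 50)
tr <- simulate_protocol(r, prot, sim_config())
pk <- measure_tail_peak(tr, 2, blank_ms = 0)
c(pk$I_tail_peak_uA, tail_ratio(tr, 2, t_end_ms = 2, blank_ms = 0))
#> [1] -1.110  0.263
```

A simulated activation step to +50 mV followed by repolarization to
−100 mV yields a −1.11 µA inward tail whose fraction remaining 2 ms after
the peak is 0.263 — the tail-ratio statistic that summarizes deactivation
speed without committing to an exponential order.

## Command line

A thin CLI wraps the same functions (`inst/exec/hergate`):

```sh
Rscript inst/exec/hergate pipeline --seed 1 --out run1
Rscript inst/exec/hergate fit-tails --in tail.csv --out fit.json --order auto
```

`pipeline` generates the full synthetic study bundle (split, N-del, C-del
and D540K archetypes under control and drug parameter sets), runs every
analysis and writes per-dataset fit JSONs plus a tidy `summary.csv`; runs
are reproducible from the manifest and seeds alone.

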