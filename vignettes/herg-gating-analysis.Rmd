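---
title: "Modeling hERG1 gating and activator-modified deactivation with hergate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hERG1 gating and activator-modified deactivation with hergate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergate)
```

## The scientific problem

hERG1 (Kv11.1) channels conduct the cardiac rapid delayed-rectifier current
I~Kr~. They open on depolarization and close ("deactivate") unusually slowly
on repolarization; compounds such as RPR260243 that further slow deactivation
increase repolarizing current and are candidate antiarrhythmics. Two-electrode
voltage-clamp experiments on *Xenopus* oocytes expressing wild-type or
engineered hERG1a channels (split channels severed at the S4-S5 linker,
N- or C-terminal deletions, the hyperpolarization-opened D540K mutant)
characterize such compounds through a small set of standard quantitative
analyses. `hergate` implements that analysis stack as reusable, tested code,
together with a kinetic simulator and seeded synthetic-data generators so
that every stage can be exercised and validated without access to raw
recordings.

## The equilibrium gating model

The voltage dependence of activation is described by a six-state sequential
scheme

$$C_0 \leftrightarrow C_1 \leftrightarrow C_2 \leftrightarrow C_3
  \leftrightarrow C_4 \leftrightarrow O,$$

four identical, independent voltage-sensor transitions followed by one
concerted pore-opening step. Both equilibrium constants are written in the
closing direction and carry exponential voltage dependence,

$$K(V) = K(0)\,e^{-z_1 FV/RT}, \qquad K_o(V) = K_o(0)\,e^{-z_2 FV/RT},$$

with effective charges $z_1, z_2 > 0$, so depolarization drives both toward
zero and the channel opens. Because the four sensors are independent and
identical, the closed states are binomially weighted and the open
probability has the closed form

$$\frac{g}{g_{max}} = \Big[\,1 + K_o + 4K_oK + 6K_oK^2 + 4K_oK^3 + K_oK^4
  \Big]^{-1} = \big[1 + K_o(1+K)^4\big]^{-1}.$$

The successive pairwise equilibrium constants implied by this weighting are
$K/4$, $2K/3$, $3K/2$ and $4K$ (toward $C_0$): this binomial assignment is
the unique one that reproduces the closed-form denominator, and it is the
reading adopted throughout the package. `state_occupancies()` evaluates the
full six-state distribution on the log scale (log-sum-exp), so extreme
voltages saturate to the limiting distribution instead of overflowing;
`po_equilibrium()` evaluates the closed form independently, and the identity
of the two code paths to 1e-12 is a standing regression test.

```{r}
ctx <- thermo_context()            # 22 degrees C by default
ctrl <- gating_params(K0 = 0.155, z1 = 1.71, Ko0 = 0.32, z2 = 0.73)
po_equilibrium(ctrl, 0, ctx)       # ~0.637 at 0 mV
```

Temperature enters only through $F/RT$. Recording temperature is a
configurable `thermo_context()` parameter with a default of 295.15 K
(22 °C), a conventional room temperature for oocyte work.

## The kinetic lift

The equilibrium model constrains only *ratios* of rates. To simulate
time-dependent currents the package lifts it to a birth-death Q-matrix: the
per-subunit activation rate is $\alpha(V) = a_c e^{+s z_1 FV/RT}$ and the
deactivation rate $\beta(V) = \alpha(V) K(V)$, with multiplicities
$4\alpha, 3\alpha, 2\alpha, \alpha$ forward and $\beta, 2\beta, 3\beta,
4\beta$ backward, and analogously $(a_o, z_2, K_o)$ for the concerted step.
The parameter $s \in [0,1]$ (`charge_split`, default 0.5) apportions each
effective charge between the forward and backward rate. Any choice of
$a_c$, $a_o$, $s$ leaves the stationary distribution — hence every
steady-state G-V — unchanged; this invariance is tested explicitly. Default
base rates ($a_c = 1$, $a_o = 0.5$ ms$^{-1}$) put control-like deactivation
at strongly negative potentials on the millisecond scale. Absolute simulated
time constants are otherwise not comparable to experimental ones: the
equilibrium data the model parameters come from carry no kinetic
information, which is why printed time constants are emulated directly with
exponential mixtures (below) rather than through the simulator.

Propagation across each constant-voltage epoch uses the matrix exponential
(`Matrix::expm`), exact for a time-homogeneous generator; a fine-step
Runge-Kutta integration (deSolve) is kept in the test suite as an
independent oracle at 1e-6. The simulated current is mean-field,
$I(t) = N \gamma P_O(t) (V - E_{rev})$, with optional additive Gaussian
noise — single-channel stochasticity, capacitance transients, leak and
series-resistance artifacts are deliberately not modeled. The measurement
operators accept a blanking window so the same code paths apply to real
recordings that do contain capacitive transients.

## Empirical curve families and their fitters

* **Boltzmann G-V**: $g/g_{max} = 1/(1 + e^{(V_{0.5}-V)/k})$, the standard
  two-parameter activation curve.
* **Double Boltzmann** for biphasic D540K-like G-V curves: a
  hyperpolarization-activated branch plus a depolarization-activated branch
  and a floor, $offset + A_{h}\sigma((V_{0.5,h}-V)/k_h) +
  A_{d}\sigma((V-V_{0.5,d})/k_d)$. Only the $(V_{0.5}, k)$ pairs are
  mechanistically interpreted; amplitudes and offset are free shape
  parameters. `calibrate_double_boltzmann()` solves the (linear) problem of
  choosing equal amplitudes and offset so the curve maximum is 1 and its
  trough equals a target minimum $g/g_{max}$ — the convention used to build
  generator truths when only the two midpoints and the trough are known.
  The fit reports the curve minimum over a dense grid spanning the data,
  which is the quantity conventionally quoted as "minimum g/gmax".
* **Logistic (Hill) concentration-response**:
  $y(c) = A_{max} + (A_{min}-A_{max})/(1 + (c/EC_{50})^{n_H})$, running
  from $A_{min}$ at zero dose to $A_{max}$ at saturation; for a potentiator
  $A_{max} > A_{min}$. Endpoints are free fit parameters, so inhibition
  data fit without re-coding.
* **Exponential mixtures** for tail-current decay:
  $I(t) = \sum_i A_i e^{-t/\tau_i} + C$ with 1-3 components, time constants
  reported fast-first.

All fitters use bounded Levenberg-Marquardt least squares (minpack.lm) on
unweighted residuals (the data are normalized before fitting; per-point
weights are accepted but off by default). Scale parameters — EC~50~, slope
factors, time constants, equilibrium constants — are searched on the log
scale. The Hill coefficient is bounded to (0, 10]. The four-parameter
6-state fit uses five jittered starts (fixed jitter seed, best RSS wins)
and renormalizes the model curve to its maximum over the data voltages,
matching how experimental G-V data are normalized. Exponential fits are
initialized by peeling (log-linear fit of the late phase, subtract, repeat)
with a geometric-ladder fallback, and amplitudes are first solved linearly
given the time constants. Parameter uncertainties are Jacobian-based
standard errors; they describe the local curvature of one fit, not the
between-oocyte S.E.M. of the experimental literature, and the two should
not be conflated.

Degenerate situations are flagged rather than silently absorbed: flat
dose-response data return a non-converged result, an EC~50~ driven to its
search bound is flagged, double-Boltzmann fits whose two midpoints collapse
within 5 mV are flagged, and exponential fits whose adjacent time-constant
ratio falls below 1.5 are flagged as over-parameterized.

**Model order selection** for tail decays increases the order while the
extra-sum-of-squares F-test rejects the simpler model at $\alpha = 0.05$
(the conventional criterion in electrophysiology) and the richer fit is
neither flagged degenerate nor non-converged. AICc is reported alongside
but does not decide. At a signal-to-noise ratio of 20 and time-constant
ratios of 5 or more this selects the generating order in well over 90% of
seeded replicates (tested over 100 seeds per case).

## Trace measurement operators

`measure_peak_current()` and `measure_tail_peak()` extract epoch extrema
after an optional blanking window (default 2 ms for tails; the simulator
needs none, and round-trip tests use 0). Tail decays are re-zeroed at the
tail-peak sample before fitting — peak-anchored timing is invariant to how
much of the activation step is recorded. The tail-ratio statistic
$I_{tail\text{-}end}/I_{tail\text{-}peak}$, read a fixed time after the
tail peak (2.5 s for slowly deactivating wild-type-like currents, 25 ms for
fast split-channel currents), summarizes deactivation without committing to
an exponential order; its midpoint along the return-voltage axis is located
by a Boltzmann fit with free amplitude and offset, which is more robust to
noise than interpolating the half-crossing. Tail extrema default to the
largest-magnitude convention since tails at negative return potentials are
inward; outward-positive sign metadata is available where the direction
matters. G-V datasets are assembled from tail peaks with either
normalization convention: per-condition maximum (maximum exactly 1) or a
control-condition reference (potentiated conditions may exceed 1).

## Synthetic data: what it emulates and what it does not

Generators exist for every dataset shape the pipeline consumes:
concentration-response tables, G-V tables (Boltzmann, double-Boltzmann or
6-state truth), single tail decays, simulated protocol families, and
exponential tail families with log-linear $\tau(V)$ interpolation between
anchor values. Noise is additive Gaussian only, with SD given absolutely or
as a fraction of the noiseless signal span (default 3%, a typical relative
error for normalized oocyte data); each generator resolves the fractional
SD against its own noiseless curve, then draws with a fixed seed under RNG
state preservation, so identical seeds give byte-identical datasets and
generators never disturb the session's random stream.
`gen_study_bundle()` writes a complete synthetic study — split, N-del,
C-del and D540K archetypes under control and 30 µM drug parameter sets from
`herg_conditions()` — with per-file seeds derived as master seed + file
index, recorded in a JSON manifest.

What the generators do **not** emulate: hierarchical oocyte-to-oocyte
variance (replicate noise is flat), capacitive/leak artifacts, drug-binding
kinetics (drug conditions are alternative parameter sets, not bound
states), and signal-dependent noise. Passing recovery tests therefore
demonstrate estimator correctness under the stated noise model, not
robustness to every pathology of real recordings.

Where the literature reports only some generator inputs, the remaining ones
were fixed once as plausible values and are not data-derived: Hill
endpoints are fold-change anchors ($A_{min} = 1$; $A_{max}$ = 2.5 for tail
potentiation, 1.5 for peak current, 4 for deactivation slowing), the
slow-component amplitude fraction of biexponential drug tails is 0.4
(within the reported 0.32-0.47 range), and the C-del and
hyperpolarization-route D540K time constants (15 and 50 ms) are synthetic
placeholders, identical between control and drug where the drug is known to
have no effect.

## Numerical choices and degenerate inputs

* Occupancies and open probability on the log scale; overflowing rate
  matrices raise an error advising to clip the protocol range rather than
  returning saturated garbage.
* Matrix-exponential propagation per epoch; one transition matrix per
  epoch, reused across samples.
* Optimizer tolerances are set near machine precision with a 500-iteration
  cap; noiseless recovery to 1e-6 relative is part of the acceptance suite.
* Ties and degeneracies: mixture components are returned sorted by time
  constant; exact tau duplicates are perturbed by 1 part in 1e9 only to
  keep the canonical container constructible, and such fits carry the
  over-parameterization flag.
* Datasets are validated before fitting (>= 4 distinct concentrations;
  >= 4 distinct voltages for a Boltzmann, >= 6 for double-Boltzmann and
  6-state fits; >= 10 samples per exponential component).

## Fitting policy for replicated data

Replicated synthetic datasets are fitted either pooled (all replicate rows
at once — equivalent to fitting per-voltage means under equal replication)
or per-replicate with parameter averaging. The package default in the
recovery suite mirrors common practice: per-replicate fits averaged for
time-constant experiments, pooled fits for dose-response and G-V tables.
Both routes are exposed, and for least-squares estimates on balanced
designs the pooled and fit-to-mean routes coincide.

## Known limitations

* The 6-state G-V fit is exact on noiseless data but sits on a steep
  likelihood ridge on a 13-point, −60…+60 mV grid: at a few percent
  additive noise the zero-voltage equilibrium constants have relative
  standard errors approaching 50%, strongly correlated with the charges.
  Point estimates from single noisy datasets should be treated with the
  corresponding caution (the reported standard errors make this visible);
  constraining shared parameters across conditions would be the natural
  extension but is out of scope.
* Time constants from the kinetic simulator depend on the artifact-chosen
  base rates and charge split; only their equilibrium consequences are
  literature-constrained.
* Inactivation gating is omitted entirely, as is any temperature dependence
  of rates.

## Problem sizes used by the test and acceptance suites

Recovery experiments run at the replicate counts of the emulated study
(n = 5-10), 13-19 voltage points, 80-3000 samples per tail trace; order
selection uses 100 seeds per case; the full test suite and the acceptance
script each complete in about a minute on a single CPU.
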