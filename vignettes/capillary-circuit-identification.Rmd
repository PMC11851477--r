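---
title: "Modelling capillary microcirculation as an identifiable lumped circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling capillary microcirculation as an identifiable lumped circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capfit)
```

## Motivation

Peripheral arterial disease in diabetic patients is routinely screened with
the ankle-brachial index (ABI), the ratio of ankle to brachial systolic
pressure. The ABI summarises conduit-artery perfusion but says little about
the microcirculation, where diabetic foot ulcers actually fail to heal.
`capfit` models a skin capillary as a small electrical-analogue circuit whose
components map onto physiological properties — viscous resistance, blood
inertia, vessel compliance — and identifies those components from pulsatile
flow waveforms. Changes in the fitted components (in particular, high
distal resistance and low compliance) then act as quantitative markers of
microvascular impairment that pressure measurements alone cannot resolve.

## The circuit model

The capillary is represented by a proximal resistance $R_1$ in series with an
inertance $L$, feeding a parallel pair of a distal resistance $R_2$ and a
compliance $C$. Taking the energy-storage variables as states — the inductor
momentum $x_1$ and the capacitor charge $x_2$ — and the source effort
(pressure analogue) $u$ as input, the state equations are

$$\dot{x}_1 = -\frac{R_1}{L} x_1 - \frac{1}{C} x_2 + u, \qquad
  \dot{x}_2 = \frac{1}{L} x_1 - \frac{1}{R_2 C} x_2 .$$

The reported output is the effort across the compliance, $y = x_2 / C$,
i.e. the pressure the distal bed sees. With this convention the transfer
function is

$$G(s) = \frac{1/(LC)}
       {s^2 + \left(\frac{R_1}{L} + \frac{1}{R_2 C}\right) s
            + \frac{1 + R_1/R_2}{LC}},$$

a second-order low-pass with DC gain $R_2/(R_1+R_2)$. An alternative output
convention that reports the raw first state is available through
`assemble_state_space(..., output = "first_state")`; it shares the
denominator (hence poles and stability) but not the numerator. The
capacitor-effort convention is the default because it is the one under which
the reference fitted parameters

```{r}
reference_circuit_params()
```

reproduce the reference transfer function:

```{r}
tf <- to_transfer_function(assemble_state_space(reference_circuit_params()))
tf
stability_report(tf)
```

The driving-point impedance $R_1 + i\omega L + R_2/(1 + i R_2 \omega C)$ is
exposed as `input_impedance()`; at $\omega = 0$ it reduces to $R_1 + R_2$.

The model layer is deliberately unit-agnostic: the identified components live
in consistent abstract units (ohm-like, henry-like, farad-like), while the
physiological Poiseuille resistances live on the order of $10^{16}$
Pa·s/m³. No conversion between the two scales is imposed, because none is
uniquely defined by the data the model consumes; the circuit captures the
*shape* of the dynamic response, the haemodynamic layer the physical
magnitudes.

## Haemodynamic scaling

The haemodynamics module carries the physical layer. Poiseuille's law gives
the capillary resistance $R = 8\eta l/(\pi r^4)$ from the reference geometry
(diameter 0.007 mm — the effective radius is always diameter/2 — length
0.0007 m, viscosity 0.0012 Pa·s), which evaluates to $1.43\times10^{16}$
Pa·s/m³, and the flow $Q = \Delta p/R$, which at the 25 mmHg reference
pressure evaluates to $2.34\times10^{-13}$ m³/s. Two reference arterial
values (resistance $3.02\times10^7$ Pa·s/m³, flow $5.30\times10^{-4}$ m³/s)
are treated as literature constants and never recomputed from geometry,
because the printed arterial geometry is not mutually consistent with them;
fidelity to the tabulated patient values takes precedence.

Per-patient profiles scale the ABI = 1 baseline linearly by the lower-limb
pressure: $s = p_\text{ankle}/120$. Pressures and flows scale by $s$;
resistances, being geometric, are copied unchanged. The scaling uses the
ankle (not the global ABI) because the posterior tibial artery feeding the
studied capillaries sees the lower-limb pressure. `mmHg` converts to Pa with
the factor 133.322, which preserves the tabulated flows to 6 significant
figures. Reported tables round pressures to 4 and flows to 3 significant
figures; full precision is kept internally.

## Waveform synthesis

The identification signals emulate a resting heart rate of 72 beats per
minute: heart period $T_H = 60/72$ s with systole occupying $T_s = 0.4\,T_H$.
During systole the entry flow is $Q_0 \sin(2\pi t/T_s)$ (one full sine cycle
per systole, the default) or $Q_0 \sin(\pi t/T_s)$ (a single positive lobe,
`shape = "half_sine"`), and zero during diastole. The full-sine default is
retained although its negative lobe is physiologically debatable; the
half-sine variant exists precisely because of that debate, and the choice
does not affect any reported reference quantity. The default grid step is
$T_H/1000$ and fitting records span 3 cardiac cycles, an integer number of
cycles so that error integrals close at the end of a diastole.

The target (exit) signal is the same pulse delayed by 90° of the systolic
sine — a quarter of $T_s$ — with its peak set to the patient's ABI-derived
capillary flow, e.g. $1.94856\times10^{-13}$ m³/s at ankle pressure
100 mmHg.

## The fitting objective

With $e(t)$ the difference between the target and the simulated output over
the record $[0, T]$, the objective combines the integral of squared error and
the time-weighted integral of squared error,

$$\mathrm{OF} = \int_0^T e^2\,dt + \int_0^T t\,e^2\,dt,$$

both computed by the trapezoidal rule on the sampling grid. The ISE term
penalises large early errors, the ITSE term errors that persist into the
transient's tail. Before simulating, a guard rejects candidate parameter
sets that are non-positive or whose state matrix has an eigenvalue with
non-negative real part; rejected candidates (and any simulation that still
produces non-finite values) receive a fixed penalty of $10^{12}$ rather than
raising an error, so the optimizer can continue moving. For strictly
positive parameters the capillary circuit matrix is always Hurwitz-stable,
so the guard binds only at degenerate boundary candidates.

## Particle swarm optimization

The optimizer is a plain global-best particle swarm. For particle $i$ and
dimension $j$,

$$v^{i,j}_{k+1} = \omega_k v^{i,j}_k
  + c_g r_1 (\mathrm{pbest}^{i,j} - x^{i,j}_k)
  + c_s r_2 (\mathrm{gbest}^{j} - x^{i,j}_k), \qquad
  x^{i,j}_{k+1} = x^{i,j}_k + v^{i,j}_{k+1},$$

with $r_1, r_2 \sim U(0,1)$ drawn fresh per particle *and* per dimension
(per-dimension draws are the standard reading and decorrelate the search
directions). The inertia decays linearly,
$\omega_{k+1} = \omega_k + (\omega_f - \omega_0)/\texttt{max\_iter}$, from
0.9 to 0.1 across the run. Defaults: 20 particles, 500 iterations, position
bounds $[10^{-6}, 450]$ in every dimension, cognitive and social
coefficients $c_g = c_s = 2$ (the canonical choice), velocity clamp
$0.5\,(x_{\max} - x_{\min})$ per dimension, and initial velocities uniform in
$\pm 2\,(x_{\max} - x_{\min})$.

**Boundary handling.** Out-of-bounds particles are repositioned onto the
violated bound and the velocity component of the clamped dimension is
*negated* (a reflecting wall). The obvious alternative — zeroing the clamped
component — was implemented first and shown to be defective: once a
particle, its personal best and the global best coincide on a bound with
zero velocity, every term of the velocity update vanishes and that dimension
collapses permanently, pinning the swarm at non-stationary boundary points.
With reflection, the bench experiment below recovers its known parameters to
machine precision on every tested seed; with zeroing it frequently stalled
at a bound where the objective still decreased into the interior.

**Identifiability.** The four components enter the response only through the
three transfer-function coefficients $1/(LC)$, $R_1/L + 1/(R_2 C)$ and
$(1+R_1/R_2)/(LC)$, so $(R_1, R_2, L, C)$ are only *jointly* identifiable:
a one-parameter family of component sets produces the identical response.
Recovery is therefore judged on transfer-function coefficients, never on raw
components. A further practical caveat: the default full-sine pulse has zero
mean, so the record contains no DC excitation and the numerator (equivalently
the DC gain) is the most weakly determined coefficient; it is pinned only
through the start-up transient, which is why deep convergence of the swarm
matters for numerator accuracy.

## Validation bench and synthetic data

The bench circuit is a known single-resistor RLC system — series $L$ feeding
a parallel $R$–$C$ pair, states capacitor voltage and inductor current,
output the resistor current $v/R$ — with characteristic polynomial
$s^2 + s/(RC) + 1/(LC)$ and unit DC gain at $R = 1$. The sign pattern of its
state matrix is fixed by passivity: for positive components the system must
be stable with unit step gain, which resolves the convention unambiguously.
`recovery_experiment()` excites the true system $(R, L, C) = (1, 0.5, 0.25)$
with a unit step (the excitation used for its published step-response
comparisons), fits 3 parameters per seed, and reports per-parameter relative
errors plus the maximum deviation of the fitted step response as a fraction
of the true final value. Reference recoveries of this bench reported
elsewhere — $(1.0187, 0.57453, 0.17955)$ and $(1.0889, 0.42664, 0.22409)$ —
correspond to step deviations of 8–10% of final value; the present
implementation reaches machine-precision recovery on all five default seeds,
so those magnitudes are documented as context, not as targets.

`synth_fit_pair()` is the synthetic-data generator for fitting tests: it
builds the systolic-pulse input, simulates a known circuit, and optionally
adds white Gaussian noise with standard deviation expressed as a fraction of
the clean output peak, deterministically per seed. It emulates pulsatile
capillary entry/exit flow under a linear time-invariant vessel response with
stationary, uncorrelated measurement noise. It does **not** emulate real
waveform morphology (no dicrotic notch), beat-to-beat variability, baseline
drift, correlated sensor noise, or nonlinear vessel mechanics — so passing
recovery tests demonstrates correctness of the identification machinery, not
robustness to clinical signal artefacts.

## Numerical choices

* **Simulation.** The default path integrates with `deSolve::lsoda`
  (`rtol = 1e-8`, `atol = 1e-12`), interpolating the sampled input linearly.
  The fitting objective instead uses an exact per-step discretization
  (closed-form 2×2 matrix exponential, first-order hold), which is exact for
  piecewise-linear inputs, evaluates thousands of candidates per second, and
  agrees with the adaptive path to better than $10^{-6}$ relative error.
  The 2×2 inverse and exponential are computed in closed form, which remains
  robust for the badly scaled matrices extreme particles generate.
* **Step/impulse horizons.** Responses span 8 slowest time constants by
  default, enough for a settled steady state; the impulse response is
  evaluated from the exact partial-fraction expansion.
* **Routh–Hurwitz.** A zero first-column pivot is replaced by
  $\varepsilon = 10^{-9}\max|a_i|$; an all-zero row is replaced by the
  derivative of the auxiliary polynomial. The verdict is cross-checked
  against pole locations in `stability_report()`.
* **Degenerate inputs.** Signals must be uniform strictly increasing grids;
  sampling coarser than $T_s/20$ is rejected; non-finite trajectories raise
  a divergence condition carrying the blow-up time.
* **Problem sizes.** The bench runs 5 seeds on a 1001-point step record
  (~4 s horizon) at 20 particles × 500 iterations; the self-consistency
  experiment fits 3-cycle, 2501-point records at the same full default
  budget. The full default budget is used because the late, low-inertia
  phase of the linear decay is where coefficient refinement happens;
  truncating the schedule (e.g. to 150 iterations) reproducibly leaves the
  swarm on a curved valley in coefficient space with ~20% numerator error.

## Limitations

* A single two-state compartment cannot represent distributed wave
  propagation or multi-branch beds; it is a deliberately minimal descriptor.
* The identified abstract components are not convertible to physical
  Pa·s/m³ without an additional calibration the data do not provide.
* The optimizer is stochastic; per-seed results are exactly reproducible,
  but different seeds can land on different points of the identifiability
  manifold while producing indistinguishable responses.
* The patient layer reproduces tabulated clinical values by a linear
  pressure-scaling rule; it is a descriptive reconstruction, not a
  predictive perfusion model.
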