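---
title: "A conductance-based striatal fast-spiking interneuron model with calcium buffering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based striatal fast-spiking interneuron model with calcium buffering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsneuron)
```

## The model

Striatal fast-spiking (FS) interneurons are parvalbumin (PV)-expressing
GABAergic cells that fire brief action potentials at 20–200 Hz and control
the output of the striatum by inhibiting medium spiny neurons. `fsneuron`
implements a single-compartment Hodgkin–Huxley-type model of these cells in
which the calcium buffer concentration — notably PV itself — feeds back onto
excitability through small-conductance Ca²⁺-activated K⁺ (SK) channels.

Charge conservation on a 30 pF membrane gives

$$C_m \frac{dV}{dt} = -(I_{Na} + I_{Kv1} + I_{Kv3} + I_{SK} + I_{Ca} +
I_{leak}) + I_{app},$$

with six currents in the positive-outward convention (nS × mV = pA):

| current | form | role |
|---|---|---|
| $I_{Na} = g_{Na}\,m_\infty^3 h\,(V-V_{Na})$ | transient Na⁺ | spike upstroke |
| $I_{Kv1} = g_{Kv1}\,n_1^4\,(V-V_K)$ | slow delayed rectifier (Kv1-type) | subthreshold shaping |
| $I_{Kv3} = g_{Kv3}\,n_3^2\,(V-V_K)$ | fast delayed rectifier (Kv3-type) | fast repolarisation |
| $I_{SK} = g_{SK}\,k\,(V-V_K)$ | Ca²⁺-gated K⁺ | AHP, adaptation |
| $I_{Ca} = g_{Ca}\,a_\infty^2\,(V-V_{Ca})$ | high-voltage-activated Ca²⁺ | sole Ca²⁺ source |
| $I_{leak} = g_{leak}\,(V-V_{leak})$ | passive leak | R\_in = 400 MΩ |

The electrical skeleton is the FS neocortical interneuron model of Erisir,
Lau, Rudy and Leonard (1999, *J Neurophysiol* 82:2476), with the rate-function
corrections used by Mancilla et al. (2007, *J Neurosci* 27:2058). The h, n₁
and n₃ gates follow first-order kinetics
$dx/dt = \alpha_x(V)(1-x) - \beta_x(V)\,x$; the fast gates m and a are
slaved to their steady states. The α/β coefficients are shipped as *data*
(`inst/extdata/gating_rates.json`), each rate being a linoid, exponential,
sigmoid or constant template; linoid removable singularities are evaluated by
their analytic limit $C\,s$. Alternative coefficient files can be supplied to
`fs_params(rates = load_gating_rates("file.json"))`.

The HVA activation steady state is
$a_\infty = 1/(1+\exp((-6-V)/7.775))$ — half-activation at −6 mV, activating
with depolarisation as required for a high-threshold Ca²⁺ current. A time
constant expression for this gate circulates in several typographic variants;
since the gate is instantaneous in this model the choice is moot, and
`ca_activation_tau()` documents one defensible parse without using it in the
dynamics.

### SK gating and the k-exponent

SK channels are voltage-independent and sense sub-micromolar Ca²⁺. Following
the two-state scheme of Goldberg et al., the gate relaxes as
$dk/dt = (k_\infty - k)/\tau_k$ with

$$k_\infty = \frac{[\mathrm{Ca}^{2+}]_i}{K_{SK} + [\mathrm{Ca}^{2+}]_i},
\qquad
\tau_k = \frac{1}{k_{on,sk}[\mathrm{Ca}^{2+}]_i + k_{off,sk}},$$

where $K_{SK} = k_{off,sk}/k_{on,sk} = 0.2/0.4 = 0.5\ \mu M$. The τ\_k above
is the exact relaxation time of the two-state scheme; a simplified reciprocal
$1/(K_{SK} + [\mathrm{Ca}^{2+}]_i)$ (read as ms) is sometimes quoted and is
available via `fs_params(literal_tau_k = TRUE)`. Both give
indistinguishable firing behaviour here because they differ by less than a
factor ~2.5 on a gate that is fast relative to the interspike interval.

Two conventions exist for how the open fraction enters the current, linear
($g_{SK} k$) and squared ($g_{SK} k^2$). This package's reference
parameterisation uses the **linear** form (`sk_exponent = 1`): with the
squared form the SK current at interspike calcium levels (k ≈ 0.2–0.4) is
several-fold weaker, the characteristic behaviours of this cell type —
interspike SK current near 15 pA at low buffer, climbing to ~35 pA at high
buffer, spike rates dropping from ~39 to ~30 Hz across the physiological PV
range, and loss of equilibrium stability near 44 pA — are not reproduced
together, whereas the linear form recovers all of them simultaneously with
the table conductance $g_{SK} = 2$ nS. The squared convention remains
available (`fs_params(sk_exponent = 2)`) for comparison studies.

### The calcium shell and buffers

Calcium entering through $I_{Ca}$ is confined to a submembrane shell of
thickness d = 0.2 μm under the cell surface A = 3000 μm² (volume 600 μm³):

$$\frac{d[\mathrm{Ca}^{2+}]_i}{dt} = -\frac{I_{Ca}}{2FAd}
- \gamma\left([\mathrm{Ca}^{2+}]_i - [\mathrm{Ca}^{2+}]_{rest}\right)
- \frac{d[\mathrm{BCa}]_i}{dt}.$$

With pA, μm and μM units the influx factor is
$1/(2FAd) = 8.637\times10^{-3}\ \mu M\,ms^{-1}\,pA^{-1}$
(`ca_influx_factor()`), positive for inward (negative) $I_{Ca}$. Clearance is
first-order (γ = 1 ms⁻¹) towards a 0.07 μM resting level.

Three buffering schemes are implemented (`buffer_scheme()`):

* **PV-like** — one class of sites for which Ca²⁺ and Mg²⁺ compete
  (k\_on,ca = 0.1 μM⁻¹ms⁻¹, k\_off,ca = 0.001 ms⁻¹; k\_on,mg = 0.0008,
  k\_off,mg = 0.025). Mg²⁺ is held constant at 500 μM; because Ca²⁺ binding
  must wait for Mg²⁺ unbinding, PV acts slowly at rest despite the high
  affinity of the free site. The rates are primary; the derived affinities
  are K\_D,ca = 0.01 μM and K\_D,mg = 31.25 μM (commonly rounded to 31 μM).
  Only the Ca²⁺-bound pool enters the calcium balance; the Mg²⁺ pool evolves
  but exchanges no calcium.
* **slow** — single-site, EGTA-like (k\_on = 0.01 μM⁻¹ms⁻¹, K\_D = 0.1 μM).
* **fast** — single-site with metal-free-PV/BAPTA-like kinetics
  (k\_on = 0.1 μM⁻¹ms⁻¹, K\_D = 0.01 μM).

Bound pools start at chemical equilibrium with (Ca\_rest, Mg\_i)
(`equilibrium_occupancy()`, verified in the tests against brute-force ODE
relaxation) and the burn-in then removes electrical transients.

## Numerics

* **Integrator.** Classic fixed-step RK4 (`fs_integrate()`, compiled core)
  with dt = 0.01 ms; the stimulus is evaluated at substep times. Halving dt
  moves spike times by far less than 0.1 ms, and a 200-ms window of the
  100-pA step matches an adaptive reference integration (rtol = 10⁻¹⁰) to
  well under 0.5 mV — both asserted in the test suite. Recording default is
  every 5th step (50 μs), resolving the ~0.5-ms spikes while keeping 9-s
  runs compact. There is no randomness anywhere: trajectories are bitwise
  reproducible.
* **Burn-in.** 4000 ms of stimulus-free integration from a canonical state
  at −70 mV (`equilibrate()`). The model rests at −69.8 mV (leak plus the
  standing SK current at resting calcium), matching the targeted ~−70 mV
  resting potential and the 400 MΩ input resistance. When a *sustained* drive is analysed (steady-state
  firing rates, interspike statistics), the first 4 s of the drive serve as
  the equilibration and the statistics are read from the following second —
  by then the calcium envelope has reached its plateau.
* **Equilibria.** At a fixed point all gates and buffer pools are slaved to
  V and the buffer passes no net flux, so the shell calcium has the closed
  form Ca\_eq(V) = Ca\_rest − φ I\_Ca(V)/γ and equilibrium finding reduces to
  1-D root bracketing on the net membrane current (`find_equilibrium()`);
  a damped Newton iteration on the full system is the fallback. Stability
  comes from the eigenvalues of a central finite-difference Jacobian
  (relative step 10⁻⁶, floor 10⁻⁹).
* **Hopf point.** Bisection (0.1 pA) on the sign of the leading eigenvalue
  real part along the equilibrium branch, with the complex-pair character of
  the critical eigenvalue asserted (`find_hopf()`).
* **Oscillation onset.** The saddle-node of limit cycles is located by
  simulation bisection (`find_oscillation_onset()`), not by periodic-orbit
  (Floquet) continuation — simpler and adequate at ~1 pA resolution. A trial
  current is classified by the final second of a 6-s integration from a
  spiking state inherited from high current. The default classification
  demands *regular* sustained spiking (ISI CV ≤ 0.05): between the Hopf
  point and the tonic onset this model produces sparse irregular
  stuttering-like firing (ISI CV 0.2–0.4, rates 1–12 Hz), which is not the
  stable periodic orbit whose fold defines the SNLC. The `"persistent"`
  criterion (any spiking) instead finds the lower edge of that irregular
  regime, ~12 pA below. The locking boundary itself is slightly fuzzy
  (estimates move within ~1 pA as the settling window grows, suggesting
  a chaotic saddle near the fold), which sets the honest precision of this
  quantity. The CV threshold is not delicate: any value in 0.02–0.15 gives
  the same boundary.

## Analysis conventions

* **Spikes** are upward 0-mV crossings, linearly interpolated between
  samples, with a 1-ms refractory guard (FS interspike intervals here are
  always > 5 ms).
* **Mean frequency** is spikes-in-window / window-duration (31 spikes in
  1 s = 31 Hz); an ISI-based variant is available.
* **Envelopes** (`extract_envelopes()`): per interspike interval, the Ca²⁺
  extrema, SK-current extrema and buffer occupancy at the calcium minimum.
  The sequence of interval minima is the *lower envelope* — the residual
  calcium that drives SK channels between spikes.
* **Plateau**: steady-state statistics use the 4th–5th second of a 5-s
  drive (`plateau_preset()`); `plateau_window()` finds the earliest settled
  window (< 1% change per interval) when a data-driven choice is wanted.
* **Interspike SK levels** (`interspike_stats()`): the action-potential
  waveform itself takes the SK current to ~150 pA, so interspike levels are
  read on the slow segment of each interval, delimited by the standard
  rate-of-rise criterion |dV/dt| ≤ 5 mV/ms. The pre-spike maximum is the
  level the slowly climbing SK current reaches where the next spike takes
  off; widening the delimiter to 10 mV/ms lets the segment ride a few mV up
  the spike foot and raises that maximum by ~5–10%, which is the measurement
  uncertainty to keep in mind when comparing against figure-derived values.

## What the model does and does not emulate

The simulations emulate whole-cell current-clamp experiments on a striatal
FS interneuron: step (100 pA, 1–5 s) and ramp (200 pA/s) injections after a
4-s equilibration, spike trains with SK-mediated adaptation, and the
summation of per-spike calcium transients into a plateau whose level and
time-to-steady-state depend on buffer kind and concentration. Passing tests
show internal consistency of this idealised cell — they do not show that a
real FS interneuron has exactly these conductance densities. Known
simplifications, deliberate and inherited from the model family:

* single compartment; no dendrites or axon;
* a single shell with uniform calcium — no radial diffusion, no
  nano/microdomains near channels, no mobile-vs-immobile buffer competition;
* no BK channels (iberiotoxin does not affect spike width in these cells),
  no stochastic channel gating;
* Mg²⁺ fixed; the SK gate sees shell-average calcium.

The irregular firing between the Hopf point and the tonic onset is a genuine
dynamical regime of this vector field; its fine structure (and hence the
lower edge found by the `"persistent"` criterion) is the least certain part
of the model and should not be over-interpreted.

## Problem sizes

The package's own test and reproduction runs use 4-s burn-ins with 5-s
protocols at dt = 0.01 ms (9×10⁵ steps per run, ~8 state variables), a
61-point equilibrium branch over 0–120 pA, bisection to 0.1 pA (Hopf) and
0.5 pA (onset, 6-s settles), and six-concentration sweeps for the three
buffer schemes; all chosen as the smallest sizes at which the reported
quantities are converged (dt-halving and settle-time checks above).

## Worked example

```{r example, eval = FALSE}
p <- fs_params()
b <- buffer_scheme("pv", B_T = 1000)
st <- equilibrate(p, b)                          # 4-s burn-in
traj <- fs_integrate(st, p, b, build_protocol("step", 100, 5000))
sp <- detect_spikes(traj)
mean_frequency(sp, c(4000, 5000))                # steady-state rate, Hz
interspike_stats(traj, plateau_preset())         # residual Ca, SK levels
find_hopf(p, b)                                  # ~44 pA
find_oscillation_onset(p, b)$I_osc_onset         # ~66 pA
```
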