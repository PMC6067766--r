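---
title: "Methods: models, control terms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, control terms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(desynctrl)
```

# The models

`desynctrl` simulates populations of mesoscopic neuronal patches as coupled
oscillators. Two levels of description are implemented.

**Kuramoto model.** Each patch carries a phase `phi_k`; on a symmetric
(optionally weighted) network `A`,

$$\dot\phi_k = \omega_k + \frac{K}{N}\sum_j A_{kj}\sin(\phi_j - \phi_k).$$

Natural frequencies are drawn from a symmetric unimodal distribution,
Normal(1, 0.1) in the benchmark experiments. The order parameter
$R e^{i\Psi} = \frac1N \sum_j e^{i\phi_j}$ measures synchrony; on an
all-to-all network the dynamics are *exactly* the mean-field form
$\dot\phi_k = \omega_k + K R \sin(\Psi - \phi_k)$ (the self-term vanishes
because $\sin 0 = 0$; the identity is asserted to $10^{-12}$ in the tests).
Above a critical coupling $K_c$ the incoherent state destabilises and the
population locks — the model's seizure analogue.

**Stuart-Landau model.** Each patch carries a complex amplitude
$z_k = \rho_k e^{i\phi_k}$ obeying the supercritical Hopf normal form

$$\dot z_k = (1 + i\omega_k - |z_k|^2) z_k + \frac{K}{N}\sum_j A_{kj} z_j.$$

Uncoupled units relax to the unit limit cycle; in the weak-coupling,
near-equal-amplitude regime the phases follow the Kuramoto model. The
package quantifies this reduction (`km_reduction_error()`): the maximal
node-mean circular distance between matched runs shrinks as `K` decreases,
which is what licenses designing the control at the phase level and applying
it to the amplitude model.

# The desynchronising control

The control stems from a Hamiltonian embedding of the Kuramoto dynamics in
angle-action variables: the incoherent configuration corresponds to an
invariant torus whose neighbourhood turns chaotic as the oscillators lock,
and a perturbation $f \sim O(K^2)$ restores its stability. Three tiers are
implemented, each written exactly as the theory prescribes:

1. `control_full()` — the full term $h_k$ for an arbitrary symmetric
   network: a three-part bracket of frequency-difference-weighted cosine and
   sine sums scaled by $-K^2/(4N^2)$.
2. `control_alltoall()` — its all-to-all closed form
   $h_k = -\frac{K^2}{4}\left[R\tilde R_k \cos(\Psi - \Psi_k) - B_k\right]$,
   with the frequency-weighted local order parameter
   $\tilde R_k e^{i\Psi_k} = \frac1N\sum_{j\ne k} e^{i\phi_j}/(\omega_j -
   \omega_k)$ and an oscillatory-average correction $B_k$.
3. `operational_control()` — the implementable form
   $\hat h_k = -\frac{\gamma}{4} K^2 R \hat R_k \cos(\Psi - \phi_k)$, using
   only the $M$ electrode-bearing nodes: $\hat R_k$ is the $M$-sample version
   of $\tilde R_k$, the local mean-field angle is replaced by the node's own
   phase, and the gain $\gamma$ absorbs the unobserved topology. The cosine
   equals the coupling signal advanced by a quarter period, so the scheme
   realises the empirical "re-inject the signal delayed by T/4" rule without
   simulating a delay (measurement, computation and injection are treated as
   instantaneous).

Electrode signals spread through an exponentially decaying field,
$S_k = c_s \sum_l e^{-2 r_{kl}} \hat h_l$ (`stimulation_field()`), and the
controlled dynamics add $S_k$ to every phase velocity
(`controlled_km_rhs()`). For the Stuart-Landau model the same $S_k$ enters
as a pure phase torque $-i S_k z_k$, so the phase reduction of the
controlled amplitude model recovers the controlled phase model.

**Conventions fixed by exact equivalence.** The printed closed form leaves
two choices open: which diagonal terms the all-to-all substitution includes,
and whether $B_k$'s second sum carries a $1/N$. Both are fixed analytically
here: with a zero-diagonal complete adjacency, the missing $j = k$ term of
the first cosine sum cancels exactly against the missing $l = k$ term of the
third bracket, and the equivalence holds *identically* provided both sums in

$$B_k = \frac1N\left[\sum_l \cos(\phi_k-\phi_l)\cos(\Psi_l-\phi_l)\tilde R_l
+ \sum_{l\ne k} \frac{\sin(\phi_k-\phi_l)}{\omega_k-\omega_l}
R\sin(\Psi-\phi_l)\right]$$

are normalised by $1/N$. The test suite asserts
`control_full == control_alltoall` on complete graphs to $10^{-12}$; terms
with singular frequency denominators ($j = k$, $l = k$) are excluded, which
is forced, not optional.

# Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `K` | coupling strength (dimensionless) | 0.5 in benchmarks | supercritical for the benchmark ensemble |
| `sd` of `g(omega)` | frequency spread (rad/time) | 0.1 | benchmark ensemble width |
| `M` | number of microelectrodes | 20 (seizure), swept in phase diagrams | invasiveness axis |
| `gamma/4` | control gain | 4.25 (seizure), swept 2–10 | strength axis; `gamma_default()` gives the a-priori connectivity-ratio guess, which is far smaller and is a helper, not an experiment default |
| `c_s` | field strength | 1 | convention |
| `r_kl` | node-electrode distance | ring arc length on the unit circle | see "field geometry" below |
| `p`, `k_half` | Newman-Watts density and backbone | 0.85, 2 | dense small-world benchmark; `k_half` unstated in the source material, robustness across {1, 2, 5} checked in tests |
| `dt` | RK4 step (time units) | 0.01 | resolves periods ~2*pi at ~600 steps; fourth-order convergence verified |
| transient | discarded fraction for mean R | first half | quasi-stationary averaging |

# Synthetic study conditions

All experiments generate their own inputs; nothing is fitted to data. The
generator emulates: (i) a dense small-world cortical-patch topology
(ring backbone plus independent shortcut addition — always connected, unlike
rewiring constructions); (ii) Gaussian frequency heterogeneity; (iii)
physiological coupling fluctuation as a piecewise-stochastic schedule `K(t)`
redrawn every `Delta t = 100` time units (baseline mean 0.1 → linear ramp →
plateau drawn from [0.55, 0.65] → mirrored ramp-down → baseline; the
alternative plateau preset "caption", support [0.45, 0.55], is provided).
Durations default to a 50-fold time compression of the full protocol, with
`scale = 1` available: the claims concern quasi-stationary regimes and are
insensitive to segment length past equilibration, which the compressed runs
retain. It does **not** emulate: measurement noise, conduction delays,
amplitude-dependent electrode coupling, inhomogeneous tissue, or empirical
connectomes. Passing tests therefore demonstrate internal consistency of the
models and control, not clinical efficacy.

The seizure drivers pair controlled and uncontrolled runs with common random
numbers (same schedule realisation, same initial condition per repetition),
so their difference isolates the control's effect.

# Numerical choices

* **Integrator.** Fixed-step classical RK4; the control is an instantaneous
  function of the state and the schedules are piecewise constant, so
  adaptive stepping would only complicate schedule alignment. Phases are
  wrapped to `[0, 2*pi)` after every step. Halving `dt` shrinks end-state
  errors by ~2^4 (order check in the tests).
* **Control torque in the Stuart-Landau integrator.** The operational
  control enters as a pure rotation $-i S_k z_k$. When two electrode
  frequencies are accidentally close, $\hat R_k \propto 1/\min_j|\omega_j -
  \omega_k|$ can reach $10^3$–$10^4$ and the torque becomes arbitrarily
  stiff — brute-force RK4 diverges at any practical step. The integrator
  therefore applies the torque through its exact exponential,
  $z \mapsto z\,e^{-i S\,dt/2}$, Strang-split around the RK4 step of the
  remaining dynamics: unconditionally stable for rotations, $O(dt^2)$
  splitting error, and bitwise inert at `gamma = 0`. The Kuramoto integrator
  needs no such treatment (phases wrap; an overdriven node simply spins and
  decoheres, which is also the control's intended effect).
* **Non-resonance.** The control theory assumes non-resonant frequencies.
  `sample_frequencies()` enforces pairwise distinctness (gap > 1e-9,
  resampling duplicates) and exposes `min_gap` for a stronger a-priori
  bound; near-resonant pairs encountered at evaluation time raise a typed
  error naming the pair. Note that occasional large control amplitudes from
  close electrode pairs do real work: the low-gain suppression boundary of
  the phase diagram moves if they are excluded.
* **Degenerate conventions.** When `R < 1e-12` the angle `Psi` is reported
  as 0; every use multiplies by `R`, so the convention is inert. The
  identity `K_series` records the coupling applied during the step at each
  record time.
* **Onset estimation.** `critical_coupling()` averages post-transient `R`
  over repetitions per grid `K` and interpolates the threshold crossing
  (default `R = 0.5`) linearly between bracketing grid points.

# Design choices on genuinely open points

* **Electrode field geometry.** The field law `exp(-2 r)` is given but the
  geometry of `r_kl` is not. The package embeds nodes on the unit circle in
  index order (arc-length distances, `distance_mode = "ring"`), which makes
  neighbouring electrode fields overlap strongly — this is the geometry
  under which the spatially embedded seizure experiments behave as
  published. The spatially abstract all-to-all phase diagrams are run with
  `distance_mode = "isolated"` (no cross-talk; each electrode drives only
  its own node): in that benchmark electrode layout is explicitly
  immaterial, which can only hold if the field contribution is negligible or
  uniform, and a uniform field contradicts the published regime boundaries
  while a negligible one reproduces them. A `"graph"` mode (shortest-path
  hops times a length scale) and a `spacing` knob expose the full range.
* **PDF injection.** The baseline's exact equations are not printed in the
  main source; the package uses the canonical phase reduction of additive
  mean-field feedback: injected force $-(P X + D \dot X)$ through the phase
  sensitivity $-\sin\phi_k$, i.e. the additive term
  $+(P X + D\dot X)\sin\phi_k$ on stimulated nodes, with $\dot X$ computed
  analytically from the uncontrolled velocities so the right-hand side stays
  a well-defined ODE. The opposite overall sign *amplifies* the collective
  mode (verified numerically), so the sign is not a free choice. The
  comparison mapping to the Hamiltonian method is `n2 = M` and
  `P + D = gamma/4`.
* **Indices.** The R API is 1-based as usual in R; all on-disk formats
  (edge lists, adjacency CSV headers, layout JSON) are 0-based and say so.
* **`mode` of the operational control.** As printed, the control uses the
  global `(R, Psi)` (default `"global-R"`); `"sampled-R"` estimates both
  from the `M` electrode phases only, for strict operational realism.

# Known limitations

* The critical coupling of the dense small-world benchmark computes to
  ~0.2, not ~0.4: mean-field theory gives $K_c = 2/(\pi g(0)) \approx 0.16$
  for Normal(1, 0.1) frequencies, scaled by the realised edge density
  (~0.86 at `p = 0.85`) to ~0.19, and the simulated threshold crossing
  agrees. A frequency spread of ~0.2–0.25 would be needed for an onset near
  0.4. The acceptance script reports the simulated value as computed.
* The required-strength ratio between the PDF and Hamiltonian methods is
  sensitive to the strength grids: the Hamiltonian side already achieves the
  target desynchronisation at the smallest conventional gain
  (`gamma/4 = 2`) for moderate electrode counts, so its minimal strength
  saturates at the grid floor and the measured ratio (median across matched
  counts, ~7–10) exceeds the nominal five-fold range separation of the two
  conventional strength grids.
* The controlled seizure-plateau order parameter averages ~0.11–0.22 across
  master seeds at 5 repetitions — "close to 0" relative to the uncontrolled
  ~0.98, but repetition noise at this scale straddles a 0.15 cut-off.
* The electrode-count regime boundaries are reproduced with the `"isolated"`
  sweep geometry; with strong field overlap they shift substantially. Any
  quantitative statement about `M` therefore carries the field geometry as a
  hidden parameter.
* No measurement noise, delays, inertia, stochastic phase dynamics, or
  subcritical (negative bifurcation parameter) Stuart-Landau regimes.
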