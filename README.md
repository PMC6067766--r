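# desynctrl

Simulation and control of pathological synchronisation in networks of coupled
neuronal oscillators.

Hypersynchronised firing of neuronal populations underlies the symptoms of
epileptic seizures and parkinsonian tremor; closed-loop neurostimulation (as
in deep brain stimulation) aims to break that synchrony with implanted
microelectrodes, ideally using as few electrodes and as weak a signal as
possible. `desynctrl` implements a minimally invasive desynchronising control
for oscillator-network models of interacting neuronal patches, together with
the simulators and experiment drivers needed to study when and how well it
works. It is aimed at computational-neuroscience and network-dynamics
researchers who want a reproducible, seeded sandbox for closed-loop
desynchronisation protocols.

## The model and the control

Neuronal patches are modelled as `N` coupled phase oscillators (Kuramoto
model) on a symmetric, possibly weighted network `A`:

    dphi_k/dt = omega_k + (K/N) * sum_j A_kj sin(phi_j - phi_k),

with natural frequencies `omega_k ~ g(omega)` and coupling strength `K`. The
degree of synchrony is the order parameter `R exp(i Psi) = mean_j exp(i
phi_j)`: `R ~ 1` means phase-locking, `R ~ 0` incoherence. Above a critical
coupling `K_c` the network locks — the model's analogue of a seizure. The
same patches can instead carry a full amplitude-phase (Stuart-Landau / Hopf
normal form) state `z_k = rho_k exp(i phi_k)`, whose weak-coupling phase
reduction is exactly the Kuramoto model.

The control derives from a Hamiltonian embedding of the Kuramoto dynamics: a
perturbation of order `K^2` stabilises the incoherent state. Its
electrode-implementable form acts on the `M` measured nodes as

    h_k = -(gamma/4) * K^2 * R * Rhat_k * cos(Psi - phi_k),

where `Rhat_k = |(1/M) sum_{j != k} exp(i phi_j) / (omega_j - omega_k)|` is a
frequency-difference-weighted order parameter computed from the electrode
signals alone, and `gamma` is a gain. The cosine is the Kuramoto coupling
signal advanced by a quarter period — the classic "delay the measured signal
by T/4 and re-inject it" rule, here with a principled amplitude. Each
electrode's signal spreads to nearby patches through an exponentially
decaying field, `S_k = c_s * sum_l exp(-2 r_kl) h_l`. Because the control
scales as `K^2` it is negligible in the healthy (weakly coupled) regime and
switches itself on as the coupling approaches criticality — the sense in
which it is minimally invasive. A Proportional-Differential Feedback (PDF)
baseline — stimulate one subpopulation with the measured mean field of
another and its derivative — is included for comparison.

## Worked example

Suppress a locked state on a small-world network with 20 electrodes:

```r
library(desynctrl)

net   <- newman_watts(100, p = 0.85, seed = 1)   # ring backbone + shortcuts
omega <- sample_frequencies(100, mean = 1, sd = 0.1, seed = 2)
phi0  <- random_phases(100, seed = 3)

unc <- integrate_km(phi0, omega, net = net, K = 0.5, t_end = 200)
lay <- place_electrodes(net, 20, seed = 4, gamma_over_4 = 4.25)
ctl <- integrate_km(phi0, omega, net = net, K = 0.5, t_end = 200,
                    control = lay)

mean_R(unc)   # 0.958  -- K = 0.5 is supercritical: the network locks
mean_R(ctl)   # 0.150  -- same system, controlled: synchrony suppressed
```

`mean_R()` is the time-averaged order parameter after discarding the first
half of the run; 0.96 versus 0.15 is the difference between a phase-locked
and a desynchronised population at identical coupling. The seizure protocol
(`run_seizure_experiment()`) drives the same comparison through a
baseline / ramp / high-coupling-plateau / recovery coupling schedule, and
`sweep_hamiltonian()` / `sweep_pdf()` map the suppression phase diagrams over
electrode count and gain.

A thin command-line interface wraps the drivers:

```sh
Rscript exec/desynctrl seizure --model km --M 20 --gamma-over-4 4.25 \
    --reps 5 --scale 50 --seed 1 --out out/
```

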