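# blgamma

Biophysical simulation and analysis of gamma oscillations in the
basolateral amygdala (BL) network.

## The scientific problem

Gamma-band (~40-80 Hz) oscillations recorded from the basolateral amygdala
wax and wane in brief bursts and organize the timing of principal-neuron
(PN) and fast-spiking-interneuron (FSI) firing. Whether the local BL
microcircuit is itself sufficient to generate this rhythm — with its
unusually low PN firing rates, sparse PN–FSI connectivity and small
interneuron fraction — is not testable by recording alone. `blgamma`
implements a biophysically detailed network model of the rat BL that
answers this in silico, together with the extracellular forward model and
the analysis algorithms needed to compare the simulated local field
potential (LFP) with electrode recordings.

The package is aimed at computational neuroscientists who want a tested,
scriptable reimplementation of the model: multicompartment
Hodgkin–Huxley cells, distance-dependent stochastic wiring, dynamic
synapses, naturalistic afferent drive, a line-source LFP, and the
spectral / burst / entrainment toolbox.

## The model

Each compartment follows the current balance

```
C_m dV/dt = -g_L (V - E_L) - g_c (V - V_other) - sum(I_int) - sum(I_syn) + I_inj
I_int = g_cur m^p h^q (V - E_cur),   dx/dt = (x_inf(V) - x) / tau_x(V)
```

with three PN compartments (soma, apical dendrite, passive-matching
dendrite; I_Na, I_DR, I_M, I_Ca, I_NaP, I_A, I_H and a somatic Ca-gated
I_sAHP whose density — 50 vs 0.2 mS/cm² — is the sole difference between
adapting and continuous PNs) and two FSI compartments with fast-spiking
kinetics. Synapses are AMPA/NMDA/GABA_A two-state receptors
(`r' = alphaT·ON·(1-r) - beta·r`) with the NMDA magnesium block
`s(V) = 1/(1 + 0.33 e^(-0.06 V))`, short-term depression
(`D = d1·d2`, floored per class), conduction delays
`dist/v + 0.8 ms + U(-0.1,0.1) + dt`, and FSI–FSI gap junctions calibrated
to a 0.05 coupling coefficient. 27,000 cells (64% adapting PNs, 26%
continuous PNs, 10% FSIs) fill a 1.4-mm cube at 9,840 cells/mm³; 1,800
afferents each contact 40 random PNs. Background synaptic bombardment is
an Ornstein–Uhlenbeck conductance pair per cell. The LFP at any electrode
is the superposition of line-source potentials of every compartment's
transmembrane current,

```
phi = I / (4 pi sigma ds) * log| (sqrt(h²+r²) - h) / (sqrt(l²+r²) - l) |
```

scaled by the density correction `(rho_tissue / rho_model)^0.67` (default
factor 4.7). Gamma arises as a PING rhythm: PN volleys recruit FSIs whose
GABA_A feedback gates the next volley.

All fixed parameters live in editable YAML under `inst/params/`; the
methods vignette (`vignettes/bl-gamma-model.Rmd`) documents every choice
that the published description leaves open.

## Worked example

```r
library(blgamma)

# single-cell physiology
measure_passive("PN_A")
#> $v_rest [1] -70.47   $r_in [1] 139.4   $tau_m [1] 29.54

s <- simulate_cell("PN_A", amp_pA = 200, step_ms = 500)
adaptation_ratio(s$spikes)
#> $ratio [1] 1.71      $class [1] "adapting"

# reduced network with naturalistic afferent drive, LFP at the center
net <- build_network(reduced_recipe(1000), seed = 42)
aff <- surrogate_trains(make_rate_profiles(64, 12000, seed = 5),
                        draw_rate_pool(200, seed = 6), net$n_afferents, seed = 7)
tr  <- simulate_network(net, 11000, seed = 1, afferent_trains = aff,
                        electrodes = matrix(rep(net$box_um / 2, 3), 1))
gamma_peak_frequency(tr$lfp[tr$t_ms > 1000, 1])$peak_hz
#> [1] 68

detect_bursts(tr$lfp[tr$t_ms > 1000, 1])      # gamma bursts on one electrode
run_ablation(net, "fsi_pn", afferent_trains = aff)  # circuit surgery
```

`measure_passive()` reports the PN resting potential (mV), input
resistance (MΩ) and membrane time constant (ms) from a −20-pA somatic
step; the adaptation ratio is the last/first interspike-interval ratio
(>1.5 = adapting). The network example builds the published reduced
1,000-cell recipe, drives it for 11 s and returns the frequency of the
gamma bump in the center-electrode LFP after removing a 1/f^a fit — 68 Hz
here, inside the published 64 ± 8 Hz band.

Command-line front ends for simulation and LFP analysis are in
`inst/cli/`.

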