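---
title: "The BL network model: biophysics, wiring, LFP forward model and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BL network model: biophysics, wiring, LFP forward model and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model equations and their parameters, the choices we had to make where
the published description leaves freedom, the synthetic inputs that stand
in for in vivo recordings, and what the tests do and do not establish.

## The model in one paragraph

The basolateral amygdala (BL) is modeled as a cube of conductance-based
neurons: three-compartment principal neurons (PNs; soma, an apical
dendrite carrying the glutamatergic synapses, and a second dendrite sized
to match passive properties) and two-compartment fast-spiking interneurons
(FSIs). Two PN archetypes differ only in the density of a slow
Ca^2+^-dependent K^+^ conductance (50 vs 0.2 mS/cm^2^), producing adapting
(PN~A~) and continuous (PN~C~) firing. Cells are wired with
distance-dependent probabilities, AMPA/NMDA/GABA~A~ synapses with
short-term depression, and FSI-FSI gap junctions; they are driven by
extrinsic afferent spike trains and per-cell Ornstein-Uhlenbeck (OU)
background conductances. Extracellular potentials are computed from every
compartment's transmembrane current with the line-source approximation.
The network generates transient gamma-band (~60-80 Hz) activity through a
PING loop: PN volleys recruit FSIs, whose GABA~A~ feedback silences the
PNs for roughly one gamma period.

## Integration scheme

Each compartment obeys a Hodgkin-Huxley current balance; gating variables
follow first-order kinetics toward voltage- (or Ca-) dependent steady
states. The integrator uses a fixed 50-µs step with a staggered update: gating variables advance by
exponential Euler using tabulated `x_inf(V)` and `exp(-dt/tau(V))`
(0.25-mV knots, linear interpolation), then the voltage step is implicit
(backward Euler) across each cell's compartments, solved directly on the
soma-rooted star topology. Channel and synaptic conductances enter the
implicit step linearly; the NMDA magnesium-block factor `s(V)` is
evaluated at the previous step's voltage. Synapses are event-driven: a
presynaptic spike (somatic upward crossing of -20 mV, 2-ms refractory)
schedules a 1-ms transmitter pulse at each target after its conduction
delay; during the pulse the receptor open fraction is integrated exactly
per synapse, and afterwards the tail is folded into a per-compartment,
per-class exponential pool, so quiescent synapses cost nothing.
Correctness of the scheme is checked against a tolerance-controlled
`deSolve::lsoda` reference on single cells (spike count exact over a
250-ms suprathreshold step, the first spikes within 0.5 ms, interspike
intervals within 5%; the staggered fixed-step scheme has a small per-cycle
timing bias that compounds through long adapting trains) and by a
per-compartment
audit that the axially-derived transmembrane current equals capacitive +
ionic + synaptic + background current at every step.

## Channel kinetics and the constants we had to choose

The PN channel equations (transient and persistent Na, delayed rectifier,
muscarinic K, high-voltage Ca, H, and the Ca-gated sAHP) follow the
published rate expressions, including the 0.6156/(alpha+beta) time-constant
scaling of the Na gates and the unusual `50*beta/(1+alpha)` delayed-rectifier
time constant (which is positive over the whole physiological range; no
clamping is needed). Several constants are *not* published and are
documented stand-ins, frozen in `inst/params/cells.yaml`:

* **Reversal potentials** E~Na~ = 45, E~K~ = -80, E~Ca~ = 120,
  E~H~ = -43 mV (literature values for BL neuron models).
* **Leak**: the text gives R~m~ = 55 kOhm-cm^2^ while the density table
  prints a leak column implying ~23 kOhm-cm^2^. Only the text value is
  consistent with the published passive triplet (V~rest~ -70.3 mV,
  R~in~ ~140 MOhm, tau~m~ ~30 ms), so the leak is 1/55k everywhere.
* **A-type K current** (equations cited but not printed): a standard
  transient scheme, activation midpoint -50 mV (slope 10), inactivation
  -85 mV (slope 5), tau 2/20 ms.
* **Proximal dendritic channels**: the density table restricts I~M~ and
  I~NaP~ to proximal dendritic regions, but the cell has exactly one
  compartment per dendrite; those densities enter at an area-weighted
  fraction `prox_fraction = 0.35`.
* **Ca pool**: d[Ca]/dt = -k I~Ca~ - [Ca]/1000 ms with influx constant
  k = 3e-6 pool units per (mA/cm^2^ ms), and the sAHP gate's log10
  argument floored at 1e-10. The sAHP alpha/beta are read with
  `log10([Ca])` (the table's "Cai2" denoting the divalent ion), giving
  activation that grows with calcium.

E~H~, `prox_fraction`, the A-type shape and k were calibrated once against
the published *cell-level* constraints only - the passive triplet, an
adaptation ratio above 1.5 for PN~A~ and below it for PN~C~ on 500-ms
steps across 120-360 pA, and FSI spike width - and then frozen; network
behavior was never part of that calibration. tau~m~ is measured the way
electrophysiologists do: a free-asymptote single exponential fitted to the
first 100 ms of the charging curve, before the slow M/NaP/H creep.

The FSI spike currents are cited but not printed; we use fast-spiking
(Wang-Buzsaki-type) kinetics with phi = 5, g~Na~ = 35 and g~K~ = 9
mS/cm^2^, shifted +10 mV so the spike threshold sits near -45 mV (the
fast-spiking range reported for BL), with leak reversal -75 mV. This
satisfies both published FSI constraints (half-width < 1 ms, non-adapting
repetitive firing, last/first ISI <= 1.1 across steps) and keeps the cell
phasic - silent on background alone, responsive to coincident EPSPs.

## Synapses

Receptor kinetics use the two-state scheme `r' = alphaT*ON*(1-r) - beta*r`
with a 1-ms transmitter pulse per event. The tables print rise/decay *time
constants*; we identify `beta = 1/tau_decay` and the ON-phase time
constant `1/(alphaT+beta) = tau_rise` (unit-tested against a fine-step
integration of the same ODE and against the resulting conductance
transient's measured rise and decay). Weights are drawn per connection
from a normal distribution reading the published "Strength (mean/var.)" as
(mean, SD) - both the variance reading and a normalized-distribution role
are switchable in `inst/params/synapses.yaml` - truncated below at 5% of
the mean. Short-term plasticity uses two depressing factors (d1 = 0.9,
d2 = 0.95; tau 40/70 ms) whose product is floored at the per-class limit;
the multiplier is sampled at each presynaptic event and scales that
event's conductance transient. Facilitation machinery exists but no
published connection class uses it (f = 1). NMDA receptors carry no
short-term plasticity. Gap junctions couple FSI somata with a conductance
(0.13 nS) calibrated so two resting FSIs show the published coupling
coefficient of 0.05.

One deliberate deviation: the table prints the PN->FSI NMDA strength
identical to its AMPA strength (7/2), whereas for PN->PN the NMDA strength
is much weaker than AMPA (2/1 vs 5/3). Taken literally, the slow
(125-ms) NMDA component accumulates into a tonic, weakly Mg-blocked drive
that makes FSIs fire continuously at over 100 Hz, decoupled from PN
volleys, and the network locks to a ~36-Hz rhythm at every operating point
we tried - abolishing every published network-level result. Reading the
printed 7/2 as a duplicated AMPA figure and applying the PN->PN NMDA
proportion (2/1) restores the published phenomenology (a 64 +/- 8 Hz LFP
peak with the unmodified background-noise table). The literal value
remains available in the config.

## Wiring

Somata are placed uniformly in the cube with >25-µm spacing (rejection
sampling on a spatial grid, verified identical to brute force); archetype
labels are randomly assigned at exactly 64/26/10%, and each cell gets an
isotropic random dendrite axis. PN->PN connections are independent
Bernoulli draws with the distance-binned probabilities (3/2/1/0.5% out to
600 µm); PN-FSI pairs within 300 µm draw one of four mutually exclusive
outcomes (34% FSI->PN, 12% PN->FSI, 16% reciprocal, 38% none); FSI-FSI
pairs draw electrical coupling at 8% and chemical connectivity conditioned
on it (50/25% vs 19/3% uni/bidirectional). These rules reproduce the
published in-degrees at full scale (PN<-PN 24.98, PN<-FSI 42.6, FSI<-PN
214.8) and the published summary FSI-FSI percentages (26% overall, ~20%
uni, ~3% bi); the separately printed FSI<-FSI in-degree of 21.6 is not
consistent with those pairwise rules and is not reproduced (we get ~13).
Each of 1,800 afferents contacts 40 uniformly drawn PNs plus, with
probability 0.003, each FSI within 300 µm of any of them (union of the
target neighborhoods), yielding 2.97 +/- 1.7 extrinsic inputs per PN, ~95%
coverage and ~6 FSIs per afferent. Delays are
`distance/(1 mm/ms) + 0.8 ms + U(-0.1, 0.1) + dt`.

Reduced recipes shrink counts and the box edge together (edge ~
scale^(1/3)), preserving density, probabilities, spatial ranges and the
per-PN extrinsic in-degree; the afferent count scales with the cell count.

## Drive

Surrogate naturalistic trains pair the instantaneous-rate profile of one
donor with the mean rate of another and draw Poisson counts in 1-ms bins.
Because the in vivo donor recordings are not packaged, the donor pools are
synthetic and clearly labeled as such: mean rates are log-normal (median
~1.5 Hz, tail to ~10 Hz) and profiles are exponentiated OU processes with
a 100-ms correlation time, rescaled to a time average of exactly 1 Hz.
The OU background conductances use the published per-archetype means, SDs
and correlation times with the exact discretization (stationary mean and
SD independent of dt); negative excursions are clamped where they enter
the membrane current but not in the state, which would otherwise bias the
stationary mean.

## LFP forward model

Every compartment is a line source; the soma is a short segment along the
cell's dendritic axis, the dendrites extend from its two ends. The
potential uses the printed closed form with conductivity 0.3 S/m and a
near-axis guard of max(1 µm, segment radius). Per-compartment
transmembrane currents (capacitive + ionic + synaptic + background,
averaged over 1-ms windows) are superposed either on-line during the run
or after the fact; both paths are tested equal. The model's reduced cell
density is compensated by the factor (tissue/model density)^0.67, whose
published range 1.9-7.5 averages to the default 4.7. At reduced scale the
amplitude-vs-count exponent can be re-estimated by subsampling cells in
`compute_lfp()`; we report it rather than asserting the full-scale value.

## Analysis algorithms

Morlet spectrograms use seven-cycle wavelets on the exact quarter-octave
grid 1-256 Hz; Welch spectra use 500-ms Hamming windows advanced by
250 ms. Band phase/amplitude come from zero-phase Butterworth filtering
(order 2 for entrainment, order 4 for burst detection) followed by the
analytic signal. Single-electrode gamma bursts are excursions of the
60-80-Hz envelope above mean + 2 SD, with duration at 25% of the event
peak (a degenerate-envelope guard of 1e-4 of the mean absorbs numerical
ripple on constant-envelope inputs). The amplitude-duration map
discretizes the 64-Hz wavelet power into bins of half the mean absolute
change between successive gamma cycles (successive samples spaced one
64-Hz period - our reading of the published rule) and splits the series at
local minima of the discretized trace.

Spatiotemporal bursts use a 4-D watershed on Z-scored (optionally
edge-corrected) gamma envelopes discretized into 0.1 bins: flooding
descends level by level with a 6-neighborhood in space plus adjacency in
time (no diagonals - a conservative, documented choice), growing existing
basins plateau-aware before seeding new ones from connected components of
each level. Events require a peak above 2 Z; members below 25% of the
peak are trimmed. Features: volume (distinct sites), duration (time steps
with a member above the border), center trajectory (mean member
coordinate per step), path length (summed step displacements - note this
accumulates fringe jitter, so the tests validate the translating-blob
ground truth on the start-to-end displacement, which the function also
reports), speed (path/duration), and a bias-corrected pairwise PLV,
`sqrt(mean((n*PLV^2 - 1)/(n - 1)))` over channel pairs, around the peak.
Entrainment uses the resultant vector and the spike-count-unbiased PPC
`(n^2 RV^2 - n)/(n(n-1))`. Spike coherence Bartlett-windows the +/-128-ms
cross- and auto-correlations of 1-ms binned trains, divides in the
frequency domain, and inverse-transforms to obtain the
autocorrelation-corrected cross-correlation.

## Reduced-scale network behavior

The package's default network experiments run the published reduced
1,000-cell recipe for ~10 s, sizes chosen so the whole test suite and the
reproduction script each run on a single CPU in well under half an hour.
Finite size matters for the rhythm: a gamma cycle in the reduced model is
carried by ~25-30 PN spikes network-wide (versus ~600 at full scale), so
cycle-to-cycle variability is large and, when FSIs are driven tonically
rather than phasically, the network falls into an alternating
strong/weak-cycle pattern whose LFP peak sits near half the PING frequency.
With the synapse table read as described above, the reduced model produces
its LFP gamma bump at 64-70 Hz across seeds under the naturalistic
surrogate drive (depending on the wiring realization the subharmonic can
carry more residual power than the fundamental, so the peak finder checks
the tallest residual peak for a companion bump near twice its frequency
and reports the cycle fundamental; the rule is switchable), and the connection-ablation and two-ensemble-competition
protocols reproduce the published directions (gamma abolished without
FSI->PN inputs; rhythm slowed without FSI-FSI inhibition; the strongly
driven ensemble suppresses the weak one only when they share FSI
territory). Population rates at reduced scale run higher than the
published full-scale rates (PNs in the middle single digits of Hz, FSIs
near 100 Hz); we deliberately did not re-tune the background to force
lower rates, because the tonic conductance load required would slow the
FSI response and destroy the rhythm - at reduced scale one can match the
rhythm or the rates, not both, and the rhythm is what the network-level
checks assert.

## What the synthetic fixtures do and do not show

The surrogate drive reproduces the rate distribution, smooth rate
modulations and Poisson statistics of cortical unit ensembles, but not
their cross-correlations or state dependence; conclusions about
low-frequency LFP content (which the original work attributes partly to
correlated afferents) are outside what these fixtures can test. The
synthetic electrode-grid generator produces smooth Gaussian gamma-envelope
blobs with known amplitude, extent and motion; it validates the burst
detector's feature recovery, not the physiological realism of burst
shapes. Passing tests establish that the algorithms recover known ground
truth and published fixed points, not that the model generalizes beyond
the published operating regime.
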