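# Synaptic connection classes.
# tau_rise / tau_decay in ms, gmax in nS, strength as (mean, spread).
# Rate constants: beta = 1/tau_decay, alphaT = 1/tau_rise - 1/tau_decay, so
# that the ON-phase rise time constant of r' = alphaT*ON*(1-r) - beta*r
# equals tau_rise.  Transmitter ON window is 1 ms per presynaptic event.
#
# strength_spread_is: how the second "Strength" number is read.  "sd"
# (default) treats it as a standard deviation; "var" as a variance.  Weights
# are truncated below at trunc_frac * mean.
transmitter_on_ms: 1.0
strength_spread_is: sd
trunc_frac: 0.05
reversal: {ampa: 0.0, nmda: 0.0, gaba: -75.0}

classes:
  pn_pn:
    ampa: {tau_rise: 0.3, tau_decay: 6.9,  gmax: 1.0, strength: [5, 3]}
    nmda: {tau_rise: 3.7, tau_decay: 125.0, gmax: 0.5, strength: [2, 1]}
    stp:  {d_max_limit: 0.5, d1: 0.9, d2: 0.95, tau_d1: 40.0, tau_d2: 70.0, f: 1.0, tau_f: 1.0}
  pn_fsi:
    ampa: {tau_rise: 0.1, tau_decay: 2.4,  gmax: 1.0, strength: [7, 2]}
    # NMDA strength follows the PN-PN NMDA:AMPA proportion rather than the
    # table's duplicated AMPA figure; see the methods vignette (the printed
    # equality gives interneurons a tonic NMDA drive that abolishes the
    # published network rhythm)
    nmda: {tau_rise: 3.7, tau_decay: 125.0, gmax: 0.5, strength: [2, 1]}
    stp:  {d_max_limit: 0.7, d1: 0.9, d2: 0.95, tau_d1: 40.0, tau_d2: 70.0, f: 1.0, tau_f: 1.0}
  fsi_pn:
    gaba: {tau_rise: 0.5, tau_decay: 6.8, gmax: 0.6, strength: [12, 2]}
    stp:  {d_max_limit: 0.6, d1: 0.9, d2: 0.95, tau_d1: 40.0, tau_d2: 70.0, f: 1.0, tau_f: 1.0}
  fsi_fsi:
    gaba: {tau_rise: 0.5, tau_decay: 6.8, gmax: 0.2, strength: [20, 10]}
    stp: ~   # no published short-term dynamics for this class
  # Extrinsic glutamatergic afferents use the corresponding intrinsic
  # excitatory parameters (afferent synapse strengths are not published
  # separately).
  aff_pn:
    ampa: {tau_rise: 0.3, tau_decay: 6.9,  gmax: 1.0, strength: [5, 3]}
    nmda: {tau_rise: 3.7, tau_decay: 125.0, gmax: 0.5, strength: [2, 1]}
    stp:  {d_max_limit: 0.5, d1: 0.9, d2: 0.95, tau_d1: 40.0, tau_d2: 70.0, f: 1.0, tau_f: 1.0}
  aff_fsi:
    ampa: {tau_rise: 0.1, tau_decay: 2.4,  gmax: 1.0, strength: [7, 2]}
    nmda: {tau_rise: 3.7, tau_decay: 125.0, gmax: 0.5, strength: [2, 1]}
    stp:  {d_max_limit: 0.7, d1: 0.9, d2: 0.95, tau_d1: 40.0, tau_d2: 70.0, f: 1.0, tau_f: 1.0}

# FSI-FSI electrical coupling: target steady-state coupling coefficient;
# the conductance is obtained by calibration on a two-cell test.
gap_junction:
  coupling_coefficient: 0.05
  conductance: 0.142 # nS; from calibrate_gap_conductance(0.05)
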