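# Ornstein-Uhlenbeck point-conductance background (per cell archetype).
# g0/sd in nS, tau in ms; sd is the stationary standard deviation.
# Conductances are clamped at zero where they enter the membrane current,
# but not in the OU state itself.
reversal: {excitatory: 0.0, inhibitory: -75.0}
pn:
  excitatory: {g0: 3.2, sd: 3.0, tau: 2.728}
  inhibitory: {g0: 21.0, sd: 8.0, tau: 10.49}
fsi:
  excitatory: {g0: 1.2, sd: 0.1, tau: 2.728}
  inhibitory: {g0: 5.7, sd: 2.6, tau: 10.49}

# Synthetic donor pools for naturalistic surrogate afferent trains
# (stand-ins for in vivo cortical unit recordings; see vignette).
surrogate:
  rate_lognormal: {meanlog: 0.405, sdlog: 0.7}   # median ~1.5 Hz, tail ~10 Hz
  profile_ou_tau_ms: 100.0                       # autocorrelation timescale
  profile_ou_sd: 0.6                             # log-rate SD before exponentiation
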