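# Network geometry, composition and wiring rules (full-scale values; reduced
# recipes rescale counts and box edge at constant density).
geometry:
  box_um: 1400.0
  min_intersoma_um: 25.0
composition:          # 64% adapting PNs, 26% continuous PNs, 10% FSIs
  pn_a: 17280
  pn_c: 7020
  fsi: 2700
pn_pn:                # distance-binned connection probability
  breaks_um: [0, 50, 100, 200, 600]
  prob: [0.03, 0.02, 0.01, 0.005]
fsi_range_um: 300.0   # hard cutoff for any connection involving an FSI
pn_fsi:               # mutually exclusive outcomes per PN-FSI pair in range
  fsi_to_pn: 0.34
  pn_to_fsi: 0.12
  reciprocal: 0.16
fsi_fsi:
  electrical: 0.08
  chemical_coupled:   {unidirectional: 0.50, bidirectional: 0.25}
  chemical_uncoupled: {unidirectional: 0.19, bidirectional: 0.03}
delay:                # Del = Dis/v + mini_del + U(-fluc, fluc) + dt, in ms
  velocity_um_per_ms: 1000.0
  mini_del: 0.8
  fluc: 0.1
  dt: 0.05
afferents:
  count: 1800
  targets_per_afferent: 40
  fsi_prob: 0.003     # per (afferent, FSI) pair, FSIs within fsi_range_um of
                      # any targeted PN (union of the target neighborhoods)
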