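# Cell archetype definitions.
# Units: um (geometry), mV, ms, mS/cm2 (densities), uF/cm2, Ohm-cm.
#
# The PN has exactly three electrical compartments (soma, apical dendrite,
# passive-matching dendrite).  Channels that are restricted to the proximal
# part of a dendrite (I_M, I_NaP) enter the single dendritic compartment at
# prox_fraction * proximal density (area-weighted spread; see vignette).
# Reversal potentials for the voltage-gated currents are literature values
# for BL neuron models (not free parameters of this package).
pn:
  axial_resistivity: 150.0
  specific_capacitance: 2.4
  leak_reversal: -75.0
  prox_fraction: 0.35
  reversals: {na: 45.0, k: -80.0, ca: 120.0, h: -43.0}
  calcium:
    tau: 1000.0          # decay time constant of the somatic Ca pool
    influx_k: 3.0e-6        # pool units per (mA/cm2 * ms); calibrated so the
                         # adapting PN crosses adaptation ratio 1.5 on a
                         # 500-ms, 200-pA step (see vignette)
    floor: 1.0e-10       # lower clamp used inside the sAHP gating log10
  compartments:
    - name: soma
      diameter: 24.75
      length: 25.0
      parent: ~
      leak: 0.01818   # 1 / (55 kOhm-cm2)
      channels: {na: 45.0, dr: 2.0, m: 2.24, h: 0.015, ca: 0.55, nap: 0.559, a: 2.0}
      sahp: {pn_a: 50.0, pn_c: 0.2}
    - name: a-dend
      diameter: 3.0
      length: 270.0
      parent: soma
      leak: 0.01818
      channels: {na: 45.0, dr: 2.0, h: 0.015, ca: 0.55, a: 2.0}
      channels_proximal: {m: 2.24, nap: 0.559}
    - name: p-dend
      diameter: 5.0
      length: 555.0
      parent: soma
      leak: 0.01818
      channels: {na: 45.0, dr: 2.0, h: 0.015, ca: 0.55}
      channels_proximal: {m: 1.792, nap: 0.447}
  synapse_targets: {excitatory: a-dend, inhibitory: soma}

# Fast-spiking interneuron.  Spike currents use fast-spiking (Wang-Buzsaki
# type) kinetics as a documented stand-in, calibrated to the two published
# constraints: spike width at half amplitude < 1 ms and non-adapting
# repetitive firing.  Passive properties as published (Rm = 20 kOhm-cm2).
fsi:
  axial_resistivity: 150.0
  specific_capacitance: 1.0
  leak_reversal: -75.0          # stand-in (not published for the FSI)
  reversals: {na: 55.0, k: -90.0}
  standin_kinetics: wang_buzsaki_phi5
  compartments:
    - name: soma
      diameter: 15.0
      length: 15.0
      parent: ~
      leak: 0.05               # 1 / (20 kOhm-cm2)
      channels: {na_fs: 35.0, dr_fs: 9.0}
    - name: fsi-dend
      diameter: 10.0
      length: 150.0
      parent: soma
      leak: 0.05
      channels: {na_fs: 35.0, dr_fs: 9.0}
  synapse_targets: {excitatory: fsi-dend, inhibitory: soma}

spike_detection:
  threshold: -20.0   # mV, upward crossing at the soma
  refractory: 2.0    # ms
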