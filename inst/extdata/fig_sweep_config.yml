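# Default in-silico sweep: model IC VIP neuron (gL = 0.7 mS/cm^2,
# ~200 MOhm at 15 um) driven by 1-s periodic input trains, 16-512 Hz at
# 4 steps/octave, AMPA-only vs AMPA+NMDA.  Units are mV, ms, mS/cm^2,
# uF/cm^2 throughout.
membrane:
  cm: 1            # uF/cm^2
  gna: 35          # mS/cm^2
  ena: 55          # mV
  gk: 9            # mS/cm^2
  ek: -90          # mV
  gl: 0.7          # mS/cm^2
  el: -65          # mV
  phi: 5
  diameter: 15     # um
synapse:
  nmda_ratio: 0.25     # NMDA peak as fraction of AMPA peak
  tau_rise_ampa: 0.2   # ms
  tau_decay_ampa: 2    # ms
  tau_rise_nmda: 5     # ms
  tau_decay_nmda: 100  # ms
  e_syn: 0             # mV
  # g_ampa omitted: calibrated per leak conductance (see integration.scale)
stimulus:
  fmin_hz: 16
  fmax_hz: 512
  steps_per_octave: 4
  duration_ms: 1000
  offset_ms: 0
  gl_values_ms_per_cm2: [0.7]
integration:
  dt_ms: 0.01
  init: steady
  calibrate: true
  scale: 0.9       # g_ampa as fraction of single-pulse spiking threshold
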