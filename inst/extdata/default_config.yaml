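# Default study conditions for the four-volume identification experiment:
# a 185 Hz growl, 2 s at 10 kHz, played through air volumes whose radii
# correspond to pipe/air diameters of 3, 4, 6 and 8 cm, in fresh water at
# 0.1 m depth.
fs: 10000
duration: 2
forcing_frequency: 185
environment:
  gamma: 1.4
  rho: 1000
  depth: 0.1
growl:
  fundamental: 185
  n_harmonics: 3
  resonator_q: 10
  onset_taper: 0.1
  snr_db: 30
  seed: 20180430
volumes:
  - radius: 1.5
    label: d3cm
  - radius: 2
    label: d4cm
  - radius: 3
    label: d6cm
  - radius: 4
    label: d8cm
input_seed: 104729
methods: [demod, cyclo]
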