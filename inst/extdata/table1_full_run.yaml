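phantom: table1_full_phantom.yaml
detector:
  n_u: 600
  n_v: 600
  pitch: 0.02
collimators:
- aspect: 50.0
  distance: 2.5
- aspect: 10.0
  distance: 2.5
- aspect: 10.0
  distance: 17.5
physics:
  energy_keV: 50.0
  l: 2.0
  target_mean_angle_deg: 4.3
n_photons: 20000000000.0
seed: 1

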