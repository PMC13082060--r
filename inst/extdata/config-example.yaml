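# Example deep3pm run configuration.
# EALs below are documented placeholders for 1300-nm excitation in cortex;
# substitute measured values for your preparation.
laser:
  f_hz: 1.0e+5          # 100 kHz
  esurface_nj: 1000     # 1 uJ at the surface -> 100 mW average power
tissue:
  layers:
    - {thickness_um: 1000, eal_um: 300}   # grey matter
    - {thickness_um: 200, eal_um: 150}    # white matter (more scattering)
    - {thickness_um: 2000, eal_um: 300}   # deep grey; last layer extends down
  depth_factor: 1.075
collection:
  geometries:
    - {name: LFOV, collection_na: 1.0, collection_fov_mm: 4, scan_fov_mm: 0.3}
    - {name: conventional, collection_na: 1.05, collection_fov_mm: 1, scan_fov_mm: 0.3}
kinetics:
  dff: 0.7
  tau_1e_s: 0.29
pipeline:
  time_constant_s: 0.29
  baseline_fraction: 0.2
  min_rate: 150
  discard_initial_s: 0
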