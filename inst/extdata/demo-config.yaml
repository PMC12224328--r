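# Demonstration pipeline configuration: synthesises every input at the
# assay's standard conditions and runs all analysis stages on them.
seed: 1
simulate:
  tracks:
    n_tracks: 60
    diffusion_coeff: 21.19   # um^2/s
    frame_rate: 25           # Hz
    duration: 12             # s
  growth:
    n0: 100
    doubling_time: 16.8      # h
    interval: 0.5            # h
    duration: 24             # h
    noise_sd: 0.05           # proportional
  profiles:
    true_shift: 214.4        # um
    channel_width: 3000
    stream_width: 1000
    smoothing_length: 50
  cascade:
    k_m: 2.9                 # mM
    k_half: 155.1            # mM
    production_v_max: 0.5    # mM/min
    decomposition_v_max: 5
    catalyst_conc: 0.1       # mg/mL
    glucose0: 5              # mM
analyze_tracks:
  max_lag: 1.0               # s
  fit_window: 1.0
analyze_profiles: {}
analyze_motility:
  cells:
    n_cells: 30
    mean_speed: 10           # um/h
    persistence_time: 2      # h
    sampling_interval: 0.5
    duration: 24
analyze_gap:
  initial_gap: 500           # um
  closure_rate: 25           # um/h
  times: [0, 6, 12, 18, 24]
  pixel_size: 5
  edge_roughness: 5
analyze_growth: {}
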