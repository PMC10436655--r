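# Demo pipeline configuration: a scaled synthetic study that exercises
# every stage (simulate -> tessellate -> aggregate -> Moran/LISA ->
# spatial and space-time scans -> KDE) in a few minutes on one CPU.
rng_seed: 7
output_dir: voroscan_demo
simulate:
  n_sections: 8
  n_seeds: 40
  total_population: 500000
  baseline_rate: 0.000496        # E[cases] = 248
  missing_days: 60
  extent: [0, 0, 8000, 8000]
  cell_size: 100
lisa:
  reps: 999
  alpha: 0.10
scan:
  replications: 199
  significance_threshold: 0.005  # floor of R = 199
  report_all: true
run_spacetime: true
run_kde: true
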