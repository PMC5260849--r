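# Demonstration pipeline configuration: a 3-year synthetic scene spanning a
# storm breakpoint, analysed end to end by run_pipeline().
seed: 42
grid:
  nx: 120
  ny: 120
  forest: [30, 90, 30, 90]     # rows/cols, half-open, 0-based, row 0 north
  damage: [40, 80, 40, 80]
start: "2008-01-01"
end: "2010-12-31"
cadence_minutes: 60
p_cloud_base: 0.3
delta_forest_jja: 0.10
cloud_boost_counts: 50
noise_sd: 2
wind_displacement_km_per_ms: 5
klaus_date: "2009-01-24"
klaus_residual_delta: 0.020
threshold: 10
window_w: 3
min_samples: 20
n_boot: 1000
wind_edges: [-1, 1]
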