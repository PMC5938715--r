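# Foreperiod condition specification (key-value config consumed by
# read_condition_config). Values mirror the reference design: foreperiods
# 0.5-3.1 s, mean 1.8 s; 25-point uniform grid (nonpredictive); Gaussian
# grids with SD 0.15 s (5 points) and 0.05 s (3 points) plus six fixed
# additional foreperiods; per-block totals 25/32/34.
nonpredictive:
  label: nonpredictive
  fp_min: 0.5
  fp_max: 3.1
  fp_mean: 1.8
  n_grid: 25
  trials_per_block: 25
weakly_predictive:
  label: weakly_predictive
  fp_min: 0.5
  fp_max: 3.1
  fp_mean: 1.8
  gaussian_sd: 0.15
  n_grid: 5
  additional_fps: [0.50, 0.93, 1.37, 2.23, 2.67, 3.10]
  trials_per_block: 32
strongly_predictive:
  label: strongly_predictive
  fp_min: 0.5
  fp_max: 3.1
  fp_mean: 1.8
  gaussian_sd: 0.05
  n_grid: 3
  additional_fps: [0.50, 0.93, 1.37, 2.23, 2.67, 3.10]
  trials_per_block: 34
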