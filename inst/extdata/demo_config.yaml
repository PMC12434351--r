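# Demo pipeline configuration: a short synthetic campaign small enough to
# run in seconds. All lengths in metres, dates as day indices, coverage in
# percent.
seed: 7
season:
  beach_length_m: 700
  n_days: 60
  neap_mean: 5.0
  spring_mean: 2.4
  longevity_mean_days: 2.8
  longevity_max_days: 9
  spring_tide_day0: 1
stations:
  - {station_id: cam01, position_m: 40,  observed_range_m: 25}
  - {station_id: cam02, position_m: 180, observed_range_m: 30}
  - {station_id: cam03, position_m: 330, observed_range_m: 20}
  - {station_id: cam04, position_m: 480, observed_range_m: 25}
  - {station_id: cam05, position_m: 620, observed_range_m: 30}
failures:
  p_fog_day: 0.023
  p_fall_day: 0.046
  capacity_days: .inf
  service_interval_days: 7
patrol_interval_days: 2
coverage_sim:
  coverage_percents: [2, 5, 10, 20, 30, 40]
  mean_tracks_per_day: 6
  n_days: 45
  n_reps: 50
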