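# Three-wave synthetic accessibility study: a 6 x 6 km jittered-grid city with
# clustered deprivation and nested CSR facility waves (29 / 33 / 78 centres),
# walked at 1 m/s with a 750 m service radius (12.5-minute budget).
city:
  synthetic:
    seed: 42
    grid_nx: 40
    grid_ny: 40
    block_size: 150
    road_jitter: 15
    n_facilities: 78
    facility_pattern: csr
    pop_total: 250000
    pop_sd_log: 0.6
    deprivation_rho: 0.8
waves:
  - year: 1996
    n_facilities: 29
  - year: 2006
    n_facilities: 33
  - year: 2016
    n_facilities: 78
walk:
  speed: 1.0
  radius: 750
  buffer_width: 50
overlay:
  method: areal
  resolution: 16
patterns:
  weights: inverse_distance
  permutations: 0
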