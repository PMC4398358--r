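# Drainage-excavation survey scenario.
# Machine data is surveyed; the subarea rectangle is a SYNTHETIC
# approximation of the graphically reported layout.
version: 1
area:
  width: 60
  depth: 36
  grid_spacing: 1
  background_level: 48.4
  working_period: 480
barriers: []
stationary_machines: []
moving_machines:
- label: D3
  lwa_full: 98.8
  p_on: 0.7
  p_off: 0.0
  p_idle: 0.3
  subarea: {x0: 14, y0: 8, width: 32, depth: 18}
  max_step: 5
worker_groups:
- label: Crew
  subarea: {x0: 18, y0: 10, width: 24, depth: 14}
simulation:
  n_steps: 1500
  seed: 1
  repeats: 3
exposure:
  exchange_rate: 3
  criterion_level: 90
  criterion_duration: 480
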