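# Piling-activity survey scenario (bungalow foundation).
# Machine data is surveyed; the subarea rectangle is a SYNTHETIC
# approximation of the graphically reported layout.
version: 1
area:
  width: 100
  depth: 60
  grid_spacing: 1
  background_level: 48.4
  working_period: 480
barriers: []
stationary_machines: []
moving_machines:
- label: D2
  lwa_full: 111.1
  p_on: 0.3
  p_off: 0.1
  p_idle: 0.6
  subarea: {x0: 30, y0: 18, width: 40, depth: 24}
  max_step: 5
worker_groups:
- label: Crew
  subarea: {x0: 35, y0: 20, width: 30, depth: 20}
simulation:
  n_steps: 1500
  seed: 1
  repeats: 3
exposure:
  exchange_rate: 3
  criterion_level: 90
  criterion_duration: 480
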