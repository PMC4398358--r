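# Oil palm mill survey scenario.
# Sound power levels and duty-cycle probabilities are the surveyed values
# (see machine_inventory.csv). Machine positions, the earth-moving
# subarea and the worker subareas are SYNTHETIC approximations: the survey
# reports the site layout only graphically, so these coordinates are
# illustrative, not measured.
version: 1
area:
  width: 143
  depth: 86
  grid_spacing: 1
  background_level: 52.2
  working_period: 480
barriers: []
stationary_machines:
- {label: S1, lwa_full: 103.9, p_on: 0.9, p_off: 0.0, p_idle: 0.1, x: 32, 'y': 58}
- {label: S2, lwa_full: 119.7, p_on: 0.9, p_off: 0.0, p_idle: 0.1, x: 40, 'y': 52}
- {label: S3, lwa_full: 105.0, p_on: 0.9, p_off: 0.0, p_idle: 0.1, x: 62, 'y': 44}
- {label: S4, lwa_full: 105.0, p_on: 0.9, p_off: 0.0, p_idle: 0.1, x: 74, 'y': 48}
- {label: S5, lwa_full: 109.2, p_on: 0.9, p_off: 0.0, p_idle: 0.1, x: 84, 'y': 40}
- {label: S6, lwa_full: 106.5, p_on: 0.5, p_off: 0.5, p_idle: 0.0, x: 102, 'y': 30}
- {label: S7, lwa_full: 106.5, p_on: 0.5, p_off: 0.5, p_idle: 0.0, x: 108, 'y': 36}
moving_machines:
- label: D1
  lwa_full: 96.8
  p_on: 0.7
  p_off: 0.0
  p_idle: 0.3
  subarea: {x0: 12, y0: 10, width: 45, depth: 22}
  max_step: 5
worker_groups:
- label: Group 1
  subarea: {x0: 30, y0: 44, width: 16, depth: 14}
- label: Group 2
  subarea: {x0: 58, y0: 32, width: 16, depth: 14}
- label: Group 3
  subarea: {x0: 94, y0: 24, width: 16, depth: 14}
simulation:
  n_steps: 1500
  seed: 1
  repeats: 3
exposure:
  exchange_rate: 3
  criterion_level: 90
  criterion_duration: 480
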