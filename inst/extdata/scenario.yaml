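# Example scenario: moderately severe disease, insured population.
# Money units are arbitrary but consistent (here: USD/year); health is on
# the QALY scale.
ranges:
  c_lo: 0         # worst consumption level
  c_hi: 100000    # best level: covers every income contemplated in sweeps
  h_lo: 0         # zero QALY gain (status quo of the sick)
  h_hi: 0.5       # full cure: h_w - h_s
curves:
  consumption: {family: power, shape: 0.7}
  health: {family: power, shape: 0.8}
scaling_constants:
  k_c: 0.3
  k_h: 0.5        # k_c + k_h < 1: health and consumption complements
health_scenario:
  pi: 0.1         # probability of the sick state
  y_s: 45000
  y_w: 50000
  h_s: 0.5
  h_w: 1.0
  dh_s: 0.25      # QALY gain from treatment in the sick state
insurance_plan:
  p: 2000         # technology cost
  coverage: 1.0   # complete coverage
  gamma: 1.0
acea_utility:
  family: interaction
  r_c: 1.0        # log consumption utility
  beta: 0.2
  r_h: 0.5
  theta: 0.01     # u_ch > 0: Hicksian q-complements
sweeps:
  factor: income
  levels: [20000, 30000, 40000, 50000]
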