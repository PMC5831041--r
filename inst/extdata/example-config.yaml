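# Example hexagait experiment: locate the direct wave gait fixed point at
# the study's stiff propulsive setting.  Units: seconds and centimetres in
# the controller block; the body block is dimensionless (lengths in units
# of the neutral leg length L).
controller:
  beta: 0.55        # duty factor
  T_sw: 10          # swing duration (s)
  s: 6              # stance line length (cm)
  d: 6              # swing arc height (cm)
  k_c: 10           # contralateral coupling gain (1/s)
  tau: 1            # foot-contact feedback lag (s)
  body_length: 40   # for speed in body lengths per second
body:
  a_star: 1
  b_star: 1
  d_star: 1
  K_star: 50        # d* K* = 50: stiff legs
  s_star: 0.3       # s*/a* = 0.3: propulsive stride
experiment:
  command: fixed-point
  gait: direct
output:
  dir: "."
  prefix: example
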