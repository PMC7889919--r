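# Default run configuration: adult-calibrated stacks at the two study
# frequencies, whole-body reference exposure level, full factor set, and the
# synthetic age-anchor tables (values other than the 35-year tie-points are
# synthetic placeholders, not literature data).
frequencies_GHz: [26, 60]
ipd: 10
ages: [5, 7, 12, 30, 35, 45, 65, 70]
factors: [thickness, permittivity, blood_flow]
mc_trials: 0
mc_anchor_ages: [7, 12, 30, 45, 65]
seed: 1
age_tables:
  skin_thickness_mm:
    age: [5, 7, 12, 30, 35, 45, 65, 70]
    mean: [1.05, 1.10, 1.22, 1.39, 1.396, 1.39, 1.20, 1.07]
  tbw:
    age: [5, 7, 12, 30, 35, 45, 65, 70]
    mean: [0.650, 0.640, 0.620, 0.605, 0.600, 0.590, 0.550, 0.540]
  body_weight_kg:
    age: [5, 7, 12, 30, 35, 45, 65, 70]
    mean: [19, 24, 41, 72, 74, 76, 74, 72]
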