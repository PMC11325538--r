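# Split/DDM protocol at the first-generation (BAT1) simulation lengths:
# 1160 ns total per calculation (restraint legs 8 x 10 ns each, transfer
# legs 20 x 9.5 ns each).
scheme = split_ddm
temperature = 298.15
blocks = 5
lambda_mode = explicit
windows = 8
window_production_ns = 10.0
window_equil_ns = 0.0

[component e]
windows = 20
window_production_ns = 9.5

[component f]
windows = 20
window_production_ns = 9.5

[component v]
windows = 20
window_production_ns = 9.5

[component w]
windows = 20
window_production_ns = 9.5
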