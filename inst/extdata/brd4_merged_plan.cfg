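# Merged/SDR protocol for the BRD4(2) fragment system: 100.8 ns total
# (four simulated components, 12 windows each, 2.1 ns per window).
scheme = merged_sdr
temperature = 298.15
blocks = 5
lambda_mode = gauss_quadrature
lambda_n = 12
search_radius = 4.0
windows = 12
window_production_ns = 2.1
window_equil_ns = 0.0
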