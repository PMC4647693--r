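# Reference one-substrate parameterisation (units: nM, seconds).
# Load with readRateConfig().
k_a: 0.01        # association rate constant, /(nM s)
k_d: 1.0         # dissociation rate constant, /s
k_c: 1.0         # ubiquitin-transfer rate constant, /s
e: 1000.0        # proteasomal degradation rate constant, /s
p_A: 0.06        # APC/C-Cdc20 accumulation rate, nM/s (linear mode)
A_const: 100.0   # constant APC/C-Cdc20 level, nM (constant mode only)
S0_init: 200.0   # initial free unmodified substrate, nM
apc_mode: linear
deub_variant: none
k_dub: 0.0
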