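label = S1
K1_mV_per_W = 117.98
K2_mV_per_W = -51.33
K3_K_per_W = 8.98
K4_K_per_W = 11.92
tau1_s = 80.8
tau2_s = 9.5
tau1_star_s = 64.4
tau2_star_s = 108.2
tau3_star_s = 0.0
tau4_star_s = 22.2
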