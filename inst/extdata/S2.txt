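label = S2
K1_mV_per_W = 132.40
K2_mV_per_W = -42.22
K3_K_per_W = 8.67
K4_K_per_W = 9.82
tau1_s = 84.0
tau2_s = 8.2
tau1_star_s = 73.5
tau2_star_s = 96.1
tau3_star_s = 0.0
tau4_star_s = 18.4
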