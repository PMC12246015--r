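strain_transfer: 0.386667
junction_amplification: 2.368749
wss_gain: 1.639983
wss_exponent: 0.558485
depth_attenuation: 0.5
sigma: 0.2
seed: 1
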