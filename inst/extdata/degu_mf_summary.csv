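group,H,delta_h,alpha0,delta_alpha_original,delta_f,delta_alpha_shuffled,delta_alpha_surrogate
CTRL,0.44,0.49,0.59,0.72,-0.01,0.25,0.65
CI,0.61,0.32,0.66,0.52,0.004,0.26,0.58
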