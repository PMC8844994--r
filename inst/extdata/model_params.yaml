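# Final-model population parameter estimates (flat config; CVs as fractions)
TVCL: 0.140
theta_PMA_CL_Hill: 7.02
theta_PMA_CL_Mat50: 197
theta_SCr_CL: 0.541
TVVc: 0.769
TVQ: 0.147
TVVp: 0.285
theta_WT_CL_Q: 0.75
theta_WT_V: 1
CVCL: 0.123
CVCL_BOV: 0.133
sigma_prop: 0.168
sigma_add: 1.76
WT_ref: 1
SCr_ref: 42
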