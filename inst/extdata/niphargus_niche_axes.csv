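pair,s_feed,s_epi,D_0.7,D_0.8,D_0.9,joint_0.7,joint_0.8,joint_0.9
NKA-NKB,0.67,0.24,0.63,0.69,0.60,0.55,0.57,0.54
NKA-NSA,0.33,0.89,0.70,0.74,0.75,0.80,0.80,0.80
NKA-NSB,0.33,0.87,0.41,0.41,0.38,0.59,0.59,0.58
NKB-NSA,0.00,0.13,0.77,0.81,0.75,0.58,0.58,0.58
NKB-NSB,0.00,0.37,0.64,0.58,0.62,0.43,0.40,0.41
NSA-NSB,1.00,0.76,0.45,0.45,0.44,0.77,0.77,0.77
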