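organ,mass_frac_bw,vasc_frac_blood,flow_frac_co,lymph_frac_flow,int_frac_vol
lung,0.014,0.055,1.000,0.0001,0.19
liver,0.025,0.100,0.245,0.0015,0.16
gut,0.017,0.028,0.150,0.0015,0.19
kidney,0.0044,0.018,0.190,0.0008,0.15
heart,0.0046,0.010,0.040,0.0008,0.16
muscle,0.40,0.140,0.170,0.0004,0.13
skin,0.047,0.050,0.050,0.0030,0.35
adipose,0.19,0.050,0.050,0.0010,0.135
rest,0.28,0.309,0.105,0.0008,0.18
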