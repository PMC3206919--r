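partition,transient_median,transient_hpd_low,transient_hpd_high,transient_bias,glob_median,glob_hpd_low,glob_hpd_high,glob_bias
12S16S,0.37,0.13,0.72,0.92,12.13,8.89,14.33,0.88
ND1,0.64,0.35,0.94,0.87,8.11,5.96,10.65,0.74
ND2,0.36,0.13,0.71,0.92,6.74,4.94,8.88,0.57
COX1,0.31,0.13,0.54,0.66,7.36,5.50,9.33,0.6
COX2,0.39,0.15,0.73,0.95,9.05,6.11,12.50,0.84
ATP8,0.41,0.17,0.76,0.94,6.29,3.54,10.17,0.73
ATP6,0.39,0.15,0.73,0.92,10.71,7.18,10.50,0.75
COX3,0.41,0.17,0.77,0.97,8.33,5.71,11.33,0.82
ND3,0.49,0.20,0.85,0.94,12.2,8.39,14.48,0.95
ND4L,0.41,0.16,0.78,0.98,10.63,6.70,13.90,0.9
ND4,0.39,0.15,0.73,0.87,7.42,5.74,9.36,0.59
ND5,0.4,0.16,0.76,0.75,8.06,6.28,9.90,0.72
CYTB,0.32,0.14,0.58,0.78,6.7,4.75,8.74,0.63
CR,0.32,0.14,0.55,0.78,8.32,5.83,12.70,0.85
subset,0.23,0.10,0.41,0.51,7.81,6.48,9.36,0.44
mitogenome,0.2,0.06,0.45,0.5,8.07,6.94,9.25,0.5
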