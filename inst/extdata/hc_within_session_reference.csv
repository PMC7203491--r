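region,mean_pct_change,lower,upper,p,printed_threshold
TE1.2,-1.15,-1.97,-0.33,0.007,0.00192
TE1.0,-0.76,-1.36,-0.15,0.016,0.00208
TE1.1,-0.53,-1.14,0.07,0.084,0.00278
TE3,-0.45,-0.78,-0.12,0.009,0.002
Ch123,-0.44,-1.86,0.99,0.538,0.00556
BA45,-0.36,-0.96,0.24,0.228,0.00357
BA44,-0.35,-1,0.29,0.276,0.00385
SF,-0.33,-0.71,0.05,0.083,0.00263
HATA,-0.21,-0.85,0.44,0.519,0.005
SUBC,-0.14,-0.63,0.36,0.579,0.00625
V1,-0.13,-0.65,0.39,0.616,0.01
V2,-0.11,-0.53,0.31,0.603,0.00833
EC,-0.1,-0.73,0.52,0.739,0.01667
CA3,-0.06,-0.34,0.21,0.636,0.0125
CA2,-0.05,-0.4,0.29,0.748,0.025
LB,0.05,-0.81,0.91,0.906,0.05
PSC3a,0.17,-0.46,0.8,0.596,0.00714
DG,0.2,-0.13,0.53,0.227,0.00333
CM,0.31,-0.1,0.71,0.133,0.00294
PSC1,0.38,-0.4,1.17,0.332,0.00417
ASTR,0.4,-0.64,1.45,0.438,0.00455
PSC2,0.43,-0.2,1.05,0.176,0.00313
CA1,0.54,0.04,1.03,0.034,0.00227
PSC3b,0.67,-0.02,1.36,0.057,0.00238
Motor4p,0.95,-0.08,1.98,0.071,0.0025
Motor4a,1.05,0.35,1.75,0.004,0.00185
Ch4,1.35,0.17,2.53,0.026,0.00217
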