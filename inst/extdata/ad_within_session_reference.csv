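region,mean_pct_change,lower,upper,p,printed_threshold
TE1.1,-1.15,-1.92,-0.38,0.004,0.00192
TE1.0,-1.01,-1.74,-0.27,0.008,0.002
TE1.2,-0.95,-1.84,-0.05,0.038,0.00263
CA2,-0.81,-1.35,-0.27,0.004,0.00185
BA45,-0.76,-1.36,-0.16,0.014,0.00208
SUBC,-0.68,-1.33,-0.03,0.042,0.00278
DG,-0.67,-1.29,-0.05,0.035,0.00238
TE3,-0.62,-1.2,-0.05,0.035,0.00227
V1,-0.56,-1.19,0.06,0.077,0.00294
BA44,-0.56,-1.28,0.16,0.124,0.00333
LB,-0.55,-1.7,0.6,0.339,0.00455
V2,-0.52,-1.01,-0.03,0.037,0.0025
CA1,-0.51,-1.48,0.46,0.298,0.00417
PSC3a,-0.48,-1.28,0.33,0.243,0.00385
CA3,-0.46,-0.85,-0.07,0.02,0.00217
EC,-0.34,-1.33,0.64,0.486,0.00556
HATA,-0.29,-0.9,0.33,0.355,0.005
SF,-0.13,-1.27,1.01,0.82,0.01
PSC3b,-0.02,-0.75,0.7,0.947,0.01667
PSC2,0.01,-0.81,0.83,0.987,0.05
CM,0.01,-0.5,0.52,0.962,0.025
PSC1,0.03,-0.67,0.73,0.93,0.0125
Motor4p,0.2,-0.57,0.97,0.607,0.00625
Ch4,0.27,-1.06,1.6,0.688,0.00833
ASTR,0.33,-1.22,1.88,0.673,0.00714
Motor4a,0.67,-0.1,1.44,0.087,0.00313
Ch123,1.24,-0.35,2.83,0.125,0.00357
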