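organ,v_frac,q_frac,f_ew,f_iw,f_nl,f_npl,alb_ratio,vasc_frac
adipose,0.190,0.050,0.135,0.017,0.853,0.0016,0.049,0.010
bone,0.086,0.050,0.100,0.346,0.017,0.0017,0.100,0.040
brain,0.020,0.120,0.162,0.620,0.039,0.0015,0.048,0.020
gut,0.017,0.150,0.282,0.475,0.038,0.0125,0.158,0.070
heart,0.005,0.040,0.320,0.456,0.014,0.0111,0.157,0.060
kidney,0.004,0.190,0.273,0.483,0.012,0.0242,0.130,0.070
liver,0.026,0.065,0.161,0.573,0.014,0.0240,0.086,0.085
lung,0.008,1.000,0.336,0.446,0.022,0.0128,0.212,0.180
muscle,0.400,0.170,0.118,0.630,0.010,0.0072,0.064,0.030
pancreas,0.001,0.010,0.120,0.664,0.041,0.0093,0.060,0.060
skin,0.037,0.050,0.382,0.291,0.060,0.0044,0.277,0.020
spleen,0.003,0.030,0.207,0.579,0.0077,0.0113,0.097,0.200
rest,0.124,0.075,0.150,0.450,0.050,0.0050,0.100,0.030
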