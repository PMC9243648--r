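layer,d_mm,mus_mm1,g,n,cb_s0.1,cb_s1,cb_s3,mua590_s0.1,mua590_s1,mua590_s3,mua780_s0.1,mua780_s1,mua780_s3
stratum corneum,0.02,100,0.86,1.5,0,0,0,0.025,0.025,0.025,0.025,0.025,0.025
vital epidermis,0.08,45,0.80,1.34,0,0,0,0.982,0.982,0.982,0.338,0.339,0.338
upper vascular plexus,0.1,35,0.95,1.39,0.020,0.20,0.60,0.050,0.233,0.471,0.026,0.030,0.035
reticular dermis,1.5,25,0.80,1.40,0.004,0.04,0.12,0.029,0.067,0.141,0.025,0.026,0.028
deep vascular plexus,0.2,30,0.95,1.38,0.010,0.10,0.30,0.036,0.129,0.285,0.025,0.027,0.031
subcutaneous fat,1.0,5,0.75,1.44,0.005,0.05,0.15,0.031,0.077,0.167,0.025,0.026,0.028
muscle,Inf,53,0.95,1.37,0.400,0.40,0.40,0.442,0.442,0.442,0.034,0.034,0.034
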