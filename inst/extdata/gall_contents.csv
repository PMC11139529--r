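batch_id,analyte,w_esm_pct,w_qams_pct,re_pct
S1,GA,2.96,NA,NA
S2,GA,3.88,NA,NA
S3,GA,3.65,NA,NA
S4,GA,8.58,NA,NA
S5,GA,4.10,NA,NA
S6,GA,3.51,NA,NA
S7,GA,3.66,NA,NA
S8,GA,3.20,NA,NA
S9,GA,3.81,NA,NA
S10,GA,4.18,NA,NA
S11,GA,3.35,NA,NA
S12,GA,4.97,NA,NA
S13,GA,5.00,NA,NA
S14,GA,4.15,NA,NA
S1,TEGG,5.79,5.70,1.52
S2,TEGG,4.43,4.36,1.53
S3,TEGG,6.78,6.67,1.65
S4,TEGG,4.51,4.44,1.60
S5,TEGG,4.43,4.36,1.49
S6,TEGG,7.19,7.07,1.66
S7,TEGG,5.56,5.47,1.63
S8,TEGG,4.24,4.17,1.62
S9,TEGG,4.83,4.76,1.54
S10,TEGG,6.20,6.10,1.57
S11,TEGG,5.43,5.34,1.67
S12,TEGG,3.02,2.97,1.52
S13,TEGG,4.66,4.59,1.62
S14,TEGG,4.20,4.14,1.49
S1,EA,0.60,0.60,0.00
S2,EA,0.69,0.68,1.47
S3,EA,0.55,0.55,0.00
S4,EA,0.98,0.98,0.00
S5,EA,0.63,0.63,0.00
S6,EA,0.45,0.45,0.00
S7,EA,0.55,0.55,0.00
S8,EA,0.64,0.64,0.00
S9,EA,0.60,0.60,0.00
S10,EA,0.52,0.52,0.00
S11,EA,0.43,0.43,0.00
S12,EA,0.89,0.89,0.00
S13,EA,0.58,0.58,0.00
S14,EA,0.35,0.35,0.00
S1,PEGG,2.82,2.86,-1.40
S2,PEGG,2.67,2.71,-1.48
S3,PEGG,3.36,3.40,-1.18
S4,PEGG,2.95,2.99,-1.34
S5,PEGG,3.05,3.09,-1.29
S6,PEGG,2.95,2.99,-1.34
S7,PEGG,3.21,3.26,-1.53
S8,PEGG,2.85,2.89,-1.38
S9,PEGG,2.67,2.71,-1.48
S10,PEGG,2.60,2.64,-1.52
S11,PEGG,2.93,2.97,-1.35
S12,PEGG,1.98,2.01,-1.49
S13,PEGG,2.43,2.46,-1.22
S14,PEGG,1.35,1.37,-1.46
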