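batch_id,pc1,pc2,composite,rank
S1,-0.98,0.17,-0.54,11
S2,0.45,-0.15,0.22,4
S3,-1.59,1.31,-0.48,9.5
S4,3.26,2.01,2.78,1
S5,0.21,0.36,0.27,3
S6,-1.84,0.45,-0.97,13
S7,-0.90,0.73,-0.28,8
S8,0.05,-0.20,-0.05,6
S9,-0.06,-0.25,-0.13,7
S10,-0.80,0.04,-0.48,9.5
S11,-1.07,-0.04,-0.68,12
S12,2.62,-0.90,1.27,2
S13,0.58,-0.50,0.17,5
S14,0.07,-3.02,-1.11,14
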