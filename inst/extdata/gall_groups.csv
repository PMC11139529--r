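batch_id,group
S1,2
S2,1
S3,2
S4,NA
S5,1
S6,2
S7,2
S8,1
S9,1
S10,2
S11,2
S12,NA
S13,1
S14,NA
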