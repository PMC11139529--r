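component,eigenvalue,contribution_pct,cumulative_pct
1,2.114,52.847,52.847
2,1.303,32.571,85.418
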