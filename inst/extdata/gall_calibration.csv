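analyte,slope,intercept,r2,range_low,range_high
GA,8.6962,10.2544,0.9999,11.40625,365
TEGG,6.84,-61.1284,0.9995,31.8125,1018
EA,43.0207,-89.5458,0.9988,3.84375,123
PEGG,5.6759,-50.9605,0.9991,13.625,436
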