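condition_set,condition,analyte,rcf,rrt
instrument,Agilent 1260,TEGG,1.6102,4.665
instrument,Shimadzu LC-20AT,TEGG,1.5406,4.410
instrument,Waters e2695,TEGG,1.6157,4.463
instrument,Agilent 1260,EA,0.2650,4.865
instrument,Shimadzu LC-20AT,EA,0.2614,4.587
instrument,Waters e2695,EA,0.2692,4.730
instrument,Agilent 1260,PEGG,1.8912,6.909
instrument,Shimadzu LC-20AT,PEGG,1.7386,6.685
instrument,Waters e2695,PEGG,1.7370,6.610
column,Agilent ZORBAX Eclipse XDB-C18,TEGG,1.6102,4.665
column,Kromasil 100-5-C18,TEGG,1.6042,4.488
column,Waters Symmetry C18,TEGG,1.6993,4.736
column,Agilent ZORBAX Eclipse XDB-C18,EA,0.2650,4.865
column,Kromasil 100-5-C18,EA,0.2630,4.799
column,Waters Symmetry C18,EA,0.2844,4.917
column,Agilent ZORBAX Eclipse XDB-C18,PEGG,1.8912,6.909
column,Kromasil 100-5-C18,PEGG,1.9000,7.050
column,Waters Symmetry C18,PEGG,1.9975,7.284
flow_rate,0.8 ml/min,TEGG,1.5568,NA
flow_rate,1.0 ml/min,TEGG,1.6102,NA
flow_rate,1.2 ml/min,TEGG,1.6086,NA
flow_rate,0.8 ml/min,EA,0.2503,NA
flow_rate,1.0 ml/min,EA,0.2650,NA
flow_rate,1.2 ml/min,EA,0.2641,NA
flow_rate,0.8 ml/min,PEGG,1.9329,NA
flow_rate,1.0 ml/min,PEGG,1.8912,NA
flow_rate,1.2 ml/min,PEGG,1.8895,NA
temperature,35C,TEGG,1.6391,NA
temperature,38C,TEGG,1.6125,NA
temperature,40C,TEGG,1.6102,NA
temperature,35C,EA,0.2685,NA
temperature,38C,EA,0.2654,NA
temperature,40C,EA,0.2650,NA
temperature,35C,PEGG,1.9068,NA
temperature,38C,PEGG,1.9007,NA
temperature,40C,PEGG,1.8912,NA
wavelength,256 nm,TEGG,1.6687,NA
wavelength,258 nm,TEGG,1.6102,NA
wavelength,260 nm,TEGG,1.5478,NA
wavelength,256 nm,EA,0.2456,NA
wavelength,258 nm,EA,0.2650,NA
wavelength,260 nm,EA,0.2644,NA
wavelength,256 nm,PEGG,1.9710,NA
wavelength,258 nm,PEGG,1.8912,NA
wavelength,260 nm,PEGG,1.8162,NA
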