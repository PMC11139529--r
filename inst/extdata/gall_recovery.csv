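analyte,sample_mg,spiked_mg,found_mg
GA,4.2044,1.9671,6.1437
GA,4.2044,1.9671,6.1403
GA,4.2044,1.9671,6.1826
GA,4.2044,2.4588,6.6634
GA,4.2044,2.4588,6.6476
GA,4.2044,2.4588,6.6874
GA,4.2044,2.9506,7.2951
GA,4.2044,2.9506,7.3175
GA,4.2044,2.9506,7.3192
TEGG,6.0999,2.4447,8.4336
TEGG,6.0999,2.4447,8.6334
TEGG,6.0999,2.4447,8.5268
TEGG,6.0999,3.0559,9.1762
TEGG,6.0999,3.0559,9.1190
TEGG,6.0999,3.0559,9.2265
TEGG,6.0999,3.6671,9.8868
TEGG,6.0999,3.6671,9.8274
TEGG,6.0999,3.6671,9.8325
EA,0.5095,0.3435,0.8486
EA,0.5095,0.3435,0.8550
EA,0.5095,0.3435,0.8601
EA,0.5095,0.4294,0.9370
EA,0.5095,0.4294,0.9338
EA,0.5095,0.4294,0.9338
EA,0.5095,0.5153,0.9974
EA,0.5095,0.5153,0.9936
EA,0.5095,0.5153,0.9985
PEGG,3.6109,1.6894,5.2590
PEGG,3.6109,1.6894,5.3795
PEGG,3.6109,1.6894,5.2563
PEGG,3.6109,2.1118,5.7668
PEGG,3.6109,2.1118,5.7444
PEGG,3.6109,2.1118,5.7147
PEGG,3.6109,2.5341,6.1903
PEGG,3.6109,2.5341,6.0287
PEGG,3.6109,2.5341,6.1097
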