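"",cultivated,ecological,construction,other
cultivated,3012.09,618.74,914.19,8.83
ecological,876.13,8476.67,305.07,16.43
construction,342.4,128.64,1664.36,5.29
other,2.04,13.1,1.7,0.04
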