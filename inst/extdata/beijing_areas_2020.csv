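class,status_2005,natural_development,object_orientation,ecosystem_priority
cultivated,4232.66,3798.57,4003.17,3903.64
ecological,9237.15,8728.13,9105.78,9266.64
construction,2885.32,3835.82,3189.32,3189.32
other,30.59,23.20,29.15,25.72
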