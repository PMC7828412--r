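parameter,value
alpha1,-0.97
alpha2,-3128.83
alpha3,4.12
alpha4,-2907.49
J0,86.86
J1,-1664.92
J2,-1593.51
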