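w2,T_298.15,T_303.15,T_308.15,T_313.15,T_318.15
0,-12.78,-12.61,-12.46,-12.34,-12.12
0.1,-12.12,-11.95,-11.80,-11.67,-11.47
0.2,-11.46,-11.29,-11.14,-11.00,-10.81
0.3,-10.80,-10.63,-10.47,-10.33,-10.16
0.4,-10.14,-9.98,-9.81,-9.67,-9.50
0.5,-9.48,-9.32,-9.15,-9.00,-8.85
0.6,-8.82,-8.66,-8.48,-8.33,-8.19
0.7,-8.16,-8.00,-7.82,-7.66,-7.54
0.8,-7.50,-7.34,-7.16,-7.00,-6.88
0.9,-6.84,-6.69,-6.50,-6.33,-6.23
1,-6.19,-6.03,-5.83,-5.66,-5.58
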