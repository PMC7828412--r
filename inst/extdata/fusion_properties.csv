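property,value,unit
Tfus,413.09,K
dHfus,20320,J_per_mol
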