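group1,group2,fst
Small,Benthic intermediate,0.028
Small,Pelagic intermediate,0.064
Small,Large,0.124
Small,C. nobilis,0.028
Small,Alpnach,0.069
Benthic intermediate,Pelagic intermediate,0.019
Benthic intermediate,Large,0.029
Benthic intermediate,C. nobilis,0.036
Benthic intermediate,Alpnach,0.022
Pelagic intermediate,Large,0.040
Pelagic intermediate,C. nobilis,0.065
Pelagic intermediate,Alpnach,0.040
Large,C. nobilis,0.107
Large,Alpnach,0.050
C. nobilis,Alpnach,0.092
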