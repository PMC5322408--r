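group,sl_range,n,h_obs,h_exp,a_r,f_is,n_ld
Small,160-235 mm,136,0.48,0.50,3.36,0.04,3
Benthic intermediate,236-320 mm,34,0.54,0.57,3.61,0.06,1
Pelagic intermediate,236-320 mm,14,0.53,0.58,3.47,0.09,2
Large,321-381 mm,51,0.57,0.59,3.55,0.03,2
C. nobilis,NA,38,0.47,0.47,2.95,0.01,3
Alpnach,NA,20,0.54,0.57,3.43,0.05,1
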