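event,lat,lon,sample_size,n_year3,n_small,n_int,n_large,n_genetics
Depth gradient,47°01'36.37",8°25'31.56",268,149,107,34,8,149
Supp. Large,47°01'36.37",8°25'31.56",8,6,NA,NA,6,6
Pelagic,47°01'34.00",8°24'47.00",66,19,NA,14,5,19
Large 1,47°01'44.71",8°23'42.23",41,16,NA,NA,16,16
Large 2,46°58'31.81",8°33'05.74",30,6,NA,NA,6,6
Large 3,46°58'24.01",8°36'29.52",57,10,NA,NA,10,10
Int 1,46°58'24.01",8°36'29.52",6,6,NA,6,NA,6
Small 1,47°02'37.04",8°23'11.80",9,3,3,NA,NA,3
Small 2,47°01'40.95",8°25'42.53",25,7,7,NA,NA,7
Small 3,46°59'53.11",8°35'05.27",63,15,15,NA,NA,14
Small n.s.,47°02'37.04",8°23'11.80",16,5,5,NA,NA,5
C. nobilis,46°59'25.55",8°29'10.24",38,NA,NA,NA,NA,38
Alpnach,46°57'52.11",8°19'10.49",20,NA,NA,NA,NA,20
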