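cluster_type,variant,rural_n,rural_pct,suburban_n,suburban_pct,urban_n,urban_pct
HH,ice_income,36,25.7,23,16.4,81,57.8
HH,ice_race,13,34.2,8,21.0,17,44.7
HH,ice_race_income,25,30.5,16,19.5,41,50.0
LL,ice_income,1,0.3,5,1.7,277,97.8
LL,ice_race,2,0.8,11,4.5,227,94.5
LL,ice_race_income,1,0.3,6,2.2,259,97.7
LH,ice_income,9,8.1,23,20.9,78,70.9
LH,ice_race,32,15.0,38,17.9,142,66.9
LH,ice_race_income,20,11.9,30,17.8,118,70.2
HL,ice_income,6,2.5,23,9.7,207,87.5
HL,ice_race,5,1.7,18,6.4,257,91.7
HL,ice_race_income,6,2.3,24,9.4,225,88.2
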