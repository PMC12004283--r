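patient,sex,age_years,etiology,diagnosis,days_since_injury,crsr
P1,M,35,Anoxia,UWS,817,7
P2,F,32,Anoxia,UWS,152,8
P3,F,31,Anoxia,UWS,281,6
P4,F,19,Anoxia,UWS,126,5
P5,M,18,Anoxia,UWS,676,7
P6,M,57,Anoxia,UWS,903,8
P7,F,73,TBI,MCS,117,11
P8,M,25,TBI,MCS,557,10
P9,M,25,TBI,MCS,2202,12
P10,F,40,TBI,MCS,8881,13
P11,M,30,TBI,MCS,210,14
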