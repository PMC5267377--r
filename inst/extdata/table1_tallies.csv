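province,district,c1,c2,m
Banteay Meanchey,Krong Poi Pet,55,48,5
Battambang,Battambang,19,16,2
Battambang,Komrieng,11,20,3
Kampong Cham,Kampong Cham,22,19,4
Phnom Penh,Chamkar Mon,19,9,5
Phnom Penh,Chbar Ampov,52,39,10
Phnom Penh,Doun Penh,31,20,4
Preah Sihanouk,Preah Sihanouk,49,25,4
Siem Reap,Siem Reap,24,25,1
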