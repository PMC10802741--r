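drug,response,n_patients,n_female,n_race_c,n_race_aa,n_race_other
MMF,responder,34,28,22,7,5
MMF,non-responder,10,9,2,7,1
AZA,responder,11,9,6,4,1
AZA,non-responder,9,9,3,5,1
HC,responder,56,53,19,34,3
HC,non-responder,14,12,4,9,1
SOC,responder,73,70,26,44,3
SOC,non-responder,25,20,8,15,2
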