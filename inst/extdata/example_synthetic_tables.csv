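study_id,outcome_id,events_t,n_t,events_c,n_c
s1,caesarean,30,100,25,100
s1,instrumental,20,100,25,100
s2,caesarean,45,150,38,150
s2,instrumental,25,150,30,150
s3,caesarean,18,80,15,80
s3,instrumental,12,80,14,80
s4,caesarean,60,220,52,220
s4,instrumental,35,220,40,220
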