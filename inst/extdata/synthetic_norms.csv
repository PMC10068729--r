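score,age_lo,age_hi,education_levels,mean,sd,scale
mmse,18,60,1|2|3,28.5,1.2,z
mmse,60,90,1|2,27.5,1.6,z
mmse,60,90,3,28.2,1.3,z
fab,18,60,1|2|3,17.0,1.1,z
fab,60,90,1|2|3,16.2,1.5,z
fcsrt_total,18,90,1|2|3,46.0,2.5,z
nct_good,18,60,1|2|3,40.0,8.0,wais_scaled
nct_good,60,90,1|2|3,31.0,7.5,wais_scaled
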