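segment,severity,class,employment_share,mean_days
adult,mild,full_time,0.1807,0.833395
adult,moderate,full_time,0.5482,0.902711
adult,severe,full_time,0.2710,2.635320
adult,mild,part_time,0.1250,3.571873
adult,moderate,part_time,0.6875,6.169067
adult,severe,part_time,0.1875,8.331527
pediatric,mild,full_time,0.333333,8.571481
pediatric,moderate,full_time,0.444444,11.786168
pediatric,severe,full_time,0.222222,10.714698
pediatric,mild,part_time,0,0
pediatric,moderate,part_time,1,66.967746
pediatric,severe,part_time,0,0
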