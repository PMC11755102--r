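dimension,level,decrement
mobility,2,0.045
mobility,3,0.085
mobility,4,0.168
mobility,5,0.210
self_care,2,0.040
self_care,3,0.090
self_care,4,0.150
self_care,5,0.200
usual_activity,2,0.035
usual_activity,3,0.070
usual_activity,4,0.140
usual_activity,5,0.170
pain_discomfort,2,0.050
pain_discomfort,3,0.110
pain_discomfort,4,0.190
pain_discomfort,5,0.230
anxiety_depression,2,0.055
anxiety_depression,3,0.115
anxiety_depression,4,0.185
anxiety_depression,5,0.215
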