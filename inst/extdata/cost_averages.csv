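segment,severity,category,mean_eur
adult,mild,treatment,116.4
adult,moderate,treatment,125.3
adult,severe,treatment,266.5
adult,mild,medical_services,61.2
adult,moderate,medical_services,158.3
adult,severe,medical_services,371.9
adult,mild,associated,71.3
adult,moderate,associated,97.7
adult,severe,associated,219.2
pediatric,mild,treatment,89
pediatric,moderate,treatment,131
pediatric,severe,treatment,206.4
pediatric,mild,associated,109
pediatric,moderate,associated,177
pediatric,severe,associated,427.3
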