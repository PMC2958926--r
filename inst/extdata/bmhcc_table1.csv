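variable,kind,role,lower,upper,weight_lo,weight_hi,group,description
TR2,numeric,dea-input,1,1.5,NA,NA,acute_care,Types of acute residential/hospital care per 100k
PR2,numeric,dea-input,9,20,NA,NA,acute_care,Places (beds) in acute residential/hospital care per 100k
UR2,numeric,dea-output,10,19,0.10,0.15,acute_care,Utilisation of acute residential/hospital care per 100k
TR4R7,numeric,dea-input,1,3.1,0.20,0.25,nonacute_hospital,Types of non-acute hospital residential care per 100k
PR4R7,numeric,dea-input,3,13,0.10,0.15,nonacute_hospital,Places in non-acute hospital residential care per 100k
UR4R7,numeric,dea-output,3,12,0.13,0.17,nonacute_hospital,Utilisation of non-acute hospital residential care per 100k
TR8R13,numeric,dea-input,3,20,0.18,0.23,residential_community,Types of non-hospital residential community care per 100k
PR8R13,numeric,dea-input,10,20,0.10,0.15,residential_community,Places in non-hospital residential community care per 100k
UR8R13,numeric,dea-output,10,40,NA,NA,residential_community,Utilisation of non-hospital residential community care per 100k
TD1D4,numeric,dea-input,3,20,0.25,0.30,day_care,Types of acute and structured day care per 100k
PD1D4,numeric,dea-input,34,100,0.025,0.05,day_care,Places in acute and structured day care per 100k
UD1D4,numeric,dea-output,33,100,0.13,0.17,day_care,Utilisation of acute and structured day care per 100k
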