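factor,description,correlation,p_value
DAI,No. of parents wearing glasses,0.061,0.002
GENDER,Gender,0.067,8.317e-4
RPR,Before mydriasis (right eye),0.091,5.991e-6
JTR,Close adjustment ability (right eye),0.108,0.001
YTR,Remote adjustment ability (right eye),0.267,1.354e-41
DRNBASE,Distant vision (right eye),0.222,4.496e-29
JG,Amount of indoor activities,0.029,0.001
YW,Amount of outdoor activities,0.030,0.032
AL,Axial length,0.106,1.546e-7
K1,Corneal curvature (left eye),0.062,0.002
K2,Corneal curvature (right eye),0.043,0.036
PULSE,Pulses per minute,0.006,0.008
TUTOR1,Participation in outdoor classes,0.282,5.417e-42
TUTOR2,Participation in indoor classes,0.203,3.620e-22
ETEST,If have regular eye examination,0.344,4.732e-63
MSMK,Whether or not smoke,0.397,1.826e-82
CELLP,Whether or not play cellphone,0.229,6.606e-28
COSTM,Whether or not write with wrong posture,0.092,1.356e-5
BED,Whether or not read in bed,0.261,2.480e-36
COLA,Frequency of drinking carbonated drinks,0.092,1.330e-5
REDM,Frequency of eating red meat,0.037,0.026
WHIM,Frequency of eating white meat,0.028,0.044
EGG,Frequency of eating eggs,0.077,2.285e-4
MILK,Frequency of drinking milk,0.077,2.672e-4
VOLUME,Daily amount of water drinking,0.096,4.681e-6
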