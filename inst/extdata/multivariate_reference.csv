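factor,description,coefficient,std_err,t_stat,p_value
DAI,No. of parents wearing glasses,-0.0218,0.033,-0.670,0.042
GENDER,Gender,-0.0418,0.047,-0.882,0.015
RPR,Before mydriasis (right eye),-0.0160,0.022,-0.735,0.207
JTR,Close adjustment ability (right eye),0.0402,0.060,0.667,0.005
YTR,Remote adjustment ability (right eye),0.2077,0.049,4.245,0.000
DRNBASE,Distant vision (right eye),-0.4191,0.200,-2.099,0.306
JG,Amount of indoor activities,-1.043,1.13,-0.922,0.035
YW,Amount of outdoor activities,-0.0099,0.014,-0.699,0.048
AL,Axial length,-0.0420,0.073,-0.578,0.003
K1,Corneal curvature (left eye),-0.2655,0.578,-0.459,0.046
K2,Corneal curvature (right eye),-0.2155,0.495,-0.435,0.036
PULSE,Pulses per minute,0.0003,0.002,0.167,0.008
TUTOR1,Participation in outdoor classes,0.0871,0.047,1.869,0.062
TUTOR2,Participation in indoor classes,0.0333,0.044,0.751,0.453
ETEST,If have regular eye examination,-0.0877,0.043,-2.042,0.401
MSMK,Whether or not smoke,-0.3692,0.266,-1.387,0.166
CELLP,Whether or not play cellphone,0.0530,0.047,1.129,0.259
COSTM,Whether or not write with wrong posture,-0.0058,0.028,-0.205,0.838
BED,Whether or not read in bed,-0.0513,0.031,-1.677,0.094
COLA,Frequency of drinking carbonated drinks,0.0041,0.025,0.163,0.007
REDM,Frequency of eating red meat,0.0167,0.022,0.761,0.044
WHIM,Frequency of eating white meat,-0.0231,0.027,-0.842,0.040
EGG,Frequency of eating eggs,-0.0054,0.025,-0.214,0.013
MILK,Frequency of drinking milk,0.0163,0.031,0.532,0.595
VOLUME,Daily amount of water drinking,-0.0041,0.032,-0.130,0.897
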