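p,R2,r
0.9,0.791,0.165
0.8,0.789,0.145
0.7,0.787,0.178
0.6,0.755,0.178
0.5,0.786,0.178
0.4,0.776,0.198
0.3,0.766,0.202
0.2,0.743,0.220
0.1,0.694,0.258
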