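bin,volunteers,days
<8,0,0
8-11,4,282
12-15,4,415
16-19,10,1276
20-23,19,2945
24-27,26,4742
28-30,17,3496
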