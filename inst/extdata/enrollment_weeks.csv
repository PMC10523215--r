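block,new,dropouts
1-4,15,0
5-8,35,3
9-12,17,0
13-16,12,0
17-20,2,0
21-24,1,0
25,1,0
26-35,0,0
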