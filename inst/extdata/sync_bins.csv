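bin,n
<1 h,40657
1-2 h,455285
3-6 h,1429176
7-12 h,2094408
13-24 h,2954687
1-2 d,1366680
3-7 d,1278007
8-14 d,519138
>14 d,372313
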