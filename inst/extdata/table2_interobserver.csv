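patient,phase,observer,aosa_deg
1,pre,1,117.13
1,post,1,128.6
2,pre,1,102.01
2,post,1,106.1
3,pre,1,114.05
3,post,1,111.43
4,pre,1,109.97
4,post,1,107.1
5,pre,1,125.32
5,post,1,125.7
1,pre,2,117.25
1,post,2,126.18
2,pre,2,103.43
2,post,2,106.75
3,pre,2,113.62
3,post,2,107.83
4,pre,2,108.05
4,post,2,111.2
5,pre,2,121
5,post,2,124.5
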