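source,target
1,0
4,0
0,1
2,1
5,2
3,2
2,3
1,3
1,4
2,4
2,5
0,5
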