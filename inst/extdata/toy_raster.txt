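neuron_id time
0 0
1 0.03
2 0.06
3 0.09
4 0.12
5 0.15
6 0.18
7 0.21
8 0.24
9 0.27
0 30
1 30.03
2 30.06
3 30.09
4 30.12
5 30.15
6 30.18
7 30.21
8 30.24
9 30.27
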