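{"N":6,"generator":"fixed_in_degree","k_mean":2,"k_sd":0,"seed":1}
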