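household_size,cutoff
1,17900
2,22300
3,27400
4,33200
5,37700
6,42500
7,47400
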