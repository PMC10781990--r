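item,external_utility
A,5
B,2
C,1
D,2
E,3
F,5
G,1
H,1
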