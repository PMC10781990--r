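item,external_utility
A01,1
A02,1
A03,1
A04,1
A05,1
A06,1
A07,1
A08,1
A09,1
A10,1
A11,1
A12,1
A13,1
A14,1
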