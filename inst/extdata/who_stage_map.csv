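category,stage
A15,3
A16,3
A17,4
B02,2
B25,4
B37,3
B38,4
B39,4
B45,4
B48,4
B49,3
B58,4
B59,4
C46,4
C83,4
R64,4
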