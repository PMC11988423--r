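class	n_shared
A3SS	12
A5SS	7
MXE	4
RI	15
SE	58
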