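true_class	control	RDX	TNT
control	26	6	0
RDX	9	100	11
TNT	2	13	81
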