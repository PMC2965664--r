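true_class	control	RDX	TNT
control	22	1	9
RDX	48	55	17
TNT	22	10	64
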