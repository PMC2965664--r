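true_class	control	RDX	TNT
control	29	2	1
RDX	7	106	7
TNT	2	14	80
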