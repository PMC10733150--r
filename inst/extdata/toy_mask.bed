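locus_000	400	600	TIW_002
locus_001	0	250	PNG_001
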