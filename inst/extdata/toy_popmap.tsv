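sample	population	continent
TIW_001	TIW	Australia
TIW_002	TIW	Australia
PNG_001	PNG	Oceania-PNG
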