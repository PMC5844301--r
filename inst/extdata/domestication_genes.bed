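chr4	25959398	25963504	LABA1
chr4	34231185	34233221	sh4
chr7	2839193	2840089	PROG1
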