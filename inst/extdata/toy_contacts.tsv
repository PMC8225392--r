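a	b
ASHL	AVAL
ASHR	AVAR
AVAL	RMDL
AVAR	RMDR
AVAL	AVAR
ASHL	ASHR
ASHL	RMDL
ASHR	RMDR
AVAL	ASHR
RMDL	RMDR
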