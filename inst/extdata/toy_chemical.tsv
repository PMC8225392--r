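pre	post	weight
ASHL	AVAL	10
ASHR	AVAR	8
AVAL	RMDL	5
AVAR	RMDR	6
M1	AVAL	1
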