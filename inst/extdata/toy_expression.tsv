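gene	AVAL	AVAR	ASHL	ASHR	RMDL	RMDR	M1
tfA	1	1	1	1	1	1	0
tfB	0	0	1	1	0	0	0
tfC	1	1	0	0	0	0	1
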