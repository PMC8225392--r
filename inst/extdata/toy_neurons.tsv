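neuron	class	category	pharyngeal
AVAL	AVA	inter	FALSE
AVAR	AVA	inter	FALSE
ASHL	ASH	sensory	FALSE
ASHR	ASH	sensory	FALSE
RMDL	RMD	motor	FALSE
RMDR	RMD	motor	FALSE
M1	M1	other	TRUE
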