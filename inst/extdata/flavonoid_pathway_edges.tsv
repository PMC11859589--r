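parent	child	label	status
phenylalanine	cinnamic acid	PAL	established
cinnamic acid	p-coumaric acid	C4H	established
p-coumaric acid	naringenin chalcone	4CL/CHS	established
naringenin chalcone	naringenin	CHI	established
naringenin	apigenin	FNS	established
apigenin	luteolin	FH	established
luteolin	tricetin	FH	established
tricetin	tricin	3'5'OMT	established
tricin	trimethoxytricetin	methylation	proposed
naringenin	dihydrokaempferol	F3H	established
dihydrokaempferol	kaempferol	FLS	established
dihydrokaempferol	leucoanthocyanidin-series	DFR	established
leucoanthocyanidin-series	anthocyanin-series	ANS	established
apigenin	apigenin-C-hexoside	hexosylation	proposed
luteolin	luteolin-C-hexoside	hexosylation	proposed
luteolin-C-hexoside	luteolin-C-hexoside-O-pentoside	pentosylation	proposed
tricin	tricin-O-hexoside	hexosylation	proposed
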