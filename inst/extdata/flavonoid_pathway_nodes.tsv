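node	formula	panel_id
phenylalanine	C9H11NO2
cinnamic acid	C9H8O2
p-coumaric acid	C9H8O3
naringenin chalcone	C15H12O5
naringenin	C15H12O5
apigenin	C15H10O5
luteolin	C15H10O6
tricetin	C15H10O7
tricin	C17H14O7
trimethoxytricetin	C18H16O7
dihydrokaempferol	C15H12O6
kaempferol	C15H10O6
leucoanthocyanidin-series
anthocyanin-series
apigenin-C-hexoside	C21H20O10
luteolin-C-hexoside	C21H20O11
luteolin-C-hexoside-O-pentoside	C26H28O15
tricin-O-hexoside	C23H24O12
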