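parent	child	label	status
indole	indolin-2-one	BX2	established
indolin-2-one	3-hydroxyindolin-2-one	BX3	established
3-hydroxyindolin-2-one	HBOA	BX4	established
HBOA	DIBOA	BX5	established
HBOA	HBOA-glucoside	BX8/BX9	established
DIBOA	DIBOA-glucoside	BX8/BX9	established
DIBOA-glucoside	TRIBOA-glucoside	BX6	established
TRIBOA-glucoside	DIMBOA-glucoside	BX7	established
DIMBOA-glucoside	HMBOA-glucoside	N-OH reduction	established
HMBOA-glucoside	HMBOA-acetyl-glucoside	acetylation	proposed
HMBOA-glucoside	HMBOA-glucoside-rhamnose	rhamnosylation	proposed
DIBOA-glucoside	DIBOA-glucoside-hexose	hexosylation	proposed
DIMBOA-glucoside	DIMBOA-glucoside-hexose	hexosylation	proposed
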