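node	formula	panel_id
indole	C8H7N
indolin-2-one	C8H7NO
3-hydroxyindolin-2-one	C8H7NO2
HBOA	C8H7NO3	HBOA
DIBOA	C8H7NO4
HBOA-glucoside	C14H17NO8	HBOA-glucoside
DIBOA-glucoside	C14H17NO9	DIBOA-glucoside
TRIBOA-glucoside	C14H17NO10
DIMBOA-glucoside	C15H19NO10	DIMBOA-glucoside
HMBOA-glucoside	C15H19NO9
DIBOA-glucoside-hexose	C20H27NO14	DIBOA-glucoside-hexose
DIMBOA-glucoside-hexose	C21H29NO15	DIMBOA-glucoside-hexose
HMBOA-acetyl-glucoside	C17H21NO10	HMBOA-acetyl-glucoside
HMBOA-glucoside-rhamnose	C21H29NO13	HMBOA-glucoside-rhamnose
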