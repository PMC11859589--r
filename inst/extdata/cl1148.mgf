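BEGIN IONS
TITLE=CL1148
PEPMASS=398.1102
CHARGE=1-
RTINSECONDS=203.4000
138.055700 40.0000
166.050400 65.0000
194.046300 100.0000
END IONS
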