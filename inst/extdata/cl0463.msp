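Name: CL0463
PrecursorMZ: 581.152200
Ion_mode: P
RetentionTime: 3.1000
Num Peaks: 5
299.055400 55.0000
329.067700 70.0000
413.087100 20.0000
431.097900 25.0000
449.110800 100.0000
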