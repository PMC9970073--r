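# Referential 10-20 montage (19 electrodes), display order top to bottom.
FP1
FP2
F3
F4
C3
C4
P3
P4
O1
O2
F7
F8
T3
T4
T5
T6
FZ
CZ
PZ
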