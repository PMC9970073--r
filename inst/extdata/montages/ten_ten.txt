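# Extended referential 10-10 montage. Editable: add or remove labels to
# match your acquisition; one electrode per line, anterior to posterior.
# T3/T4/T5/T6 are the classic names for T7/T8/P7/P8.
FP1
FPZ
FP2
AF7
AF3
AFZ
AF4
AF8
F7
F5
F3
F1
FZ
F2
F4
F6
F8
FT7
FC5
FC3
FC1
FCZ
FC2
FC4
FC6
FT8
T3
C5
C3
C1
CZ
C2
C4
C6
T4
TP7
CP5
CP3
CP1
CPZ
CP2
CP4
CP6
TP8
T5
P5
P3
P1
PZ
P2
P4
P6
T6
PO7
PO3
POZ
PO4
PO8
O1
OZ
O2
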