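label	x	y
AF3	-0.2791	0.8227
AF4	0.2791	0.8227
AF7	-0.5878	0.809
AF8	0.5878	0.809
AFZ	0	0.75
C1	-0.25	0
C2	0.25	0
C3	-0.5	0
C4	0.5	0
C5	-0.75	0
C6	0.75	0
CP1	-0.2302	-0.3059
CP2	0.2302	-0.3059
CP3	-0.4659	-0.3388
CP4	0.4659	-0.3388
CP5	-0.7065	-0.3435
CP6	0.7065	-0.3435
CPZ	0	-0.25
CZ	0	0
F1	-0.1858	0.5708
F2	0.1858	0.5708
F3	-0.3836	0.6139
F4	0.3836	0.6139
F5	-0.592	0.623
F6	0.592	0.623
F7	-0.809	0.5878
F8	0.809	0.5878
FC1	-0.2302	0.3059
FC2	0.2302	0.3059
FC3	-0.4659	0.3388
FC4	0.4659	0.3388
FC5	-0.7065	0.3435
FC6	0.7065	0.3435
FCZ	0	0.25
FP1	-0.309	0.9511
FP2	0.309	0.9511
FPZ	0	1
FT7	-0.9511	0.309
FT8	0.9511	0.309
FZ	0	0.5
O1	-0.309	-0.9511
O2	0.309	-0.9511
OZ	0	-1
P1	-0.1858	-0.5708
P2	0.1858	-0.5708
P3	-0.3836	-0.6139
P4	0.3836	-0.6139
P5	-0.592	-0.623
P6	0.592	-0.623
P7	-0.809	-0.5878
P8	0.809	-0.5878
PO3	-0.2791	-0.8227
PO4	0.2791	-0.8227
PO7	-0.5878	-0.809
PO8	0.5878	-0.809
POZ	0	-0.75
PZ	0	-0.5
T3	-1	0
T4	1	0
T5	-0.809	-0.5878
T6	0.809	-0.5878
T7	-1	0
T8	1	0
TP7	-0.9511	-0.309
TP8	0.9511	-0.309
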