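# Longitudinal bipolar 10-20 ("double banana"): two temporal chains, two
# parasagittal chains, one midline chain.
FP1-F7 = FP1 - F7
F7-T3  = F7  - T3
T3-T5  = T3  - T5
T5-O1  = T5  - O1
FP2-F8 = FP2 - F8
F8-T4  = F8  - T4
T4-T6  = T4  - T6
T6-O2  = T6  - O2
FP1-F3 = FP1 - F3
F3-C3  = F3  - C3
C3-P3  = C3  - P3
P3-O1  = P3  - O1
FP2-F4 = FP2 - F4
F4-C4  = F4  - C4
C4-P4  = C4  - P4
P4-O2  = P4  - O2
FZ-CZ  = FZ  - CZ
CZ-PZ  = CZ  - PZ
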