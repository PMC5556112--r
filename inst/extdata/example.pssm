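
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -2  -3  -4  -5  -3  -2  -4  -5  -3   1   2  -3   8  -1  -4  -3  -2  -3  -3   0    0   0   0   0   0   0   0   0   0   5  10   0  85   0   0   0   0   0   0   0  0.80 0.09
    2 K    -1   2  -1  -2  -4   1   1  -2  -1  -3  -3   6  -2  -4  -2  -1  -1  -4  -3  -3    0   5   0   0   0   5   5   0   0   0   0  80   0   0   0   5   0   0   0   0  0.75 0.12
    3 T     0  -1   0  -1  -2  -1  -1  -2  -2  -1  -2  -1  -1  -3  -2   2   6  -4  -2   0    5   0   0   0   0   0   0   0   0   0   0   0   0   0   0  15  75   0   0   5  0.62 0.10
    4 A     5  -2  -2  -3  -1  -1  -2   0  -2  -2  -2  -1  -1  -3  -1   1   0  -3  -2  -1   80   0   0   0   0   0   0   5   0   0   0   0   0   0   0  10   5   0   0   0  0.55 0.08

                      K         Lambda
Standard Ungapped    0.1347     0.3179
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1586     0.3132
PSI Gapped           0.0410     0.2670
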