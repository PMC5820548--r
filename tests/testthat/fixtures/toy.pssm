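
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V    A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    -9  -8  -7  -6  -5  -4  -3  -2  -1   0   1   2   3   4   5   6   7   8   9  10    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.45     1.00
    2 H    -8  -7  -6  -5  -4  -3  -2  -1   0   1   2   3   4   5   6   7   8   9  10  11    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.45     1.00
    3 T    -7  -6  -5  -4  -3  -2  -1   0   1   2   3   4   5   6   7   8   9  10  11  12    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.45     1.00
    4 A    -6  -5  -4  -3  -2  -1   0   1   2   3   4   5   6   7   8   9  10  11  12  13    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.45     1.00
    5 C    -5  -4  -3  -2  -1   0   1   2   3   4   5   6   7   8   9  10  11  12  13  14    0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0  0.45     1.00

                      K         Lambda
Standard Ungapped    0.1370     0.3200
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1680     0.3120
PSI Gapped           0.0410     0.2670
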