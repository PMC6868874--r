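>CTCF_like_synthetic 19-bp synthetic occupancy motif with CpG-capable columns at positions 2-3 and 12-13 (not a database matrix)
A [  7 10  5  8  6 70  8  7 72  6  5  9  4  6 64  5  9  8 55 ]
C [ 10 70  8 66 72  9 68 70  8  7  6 67  6  8  8  8 62 10 15 ]
G [  8 12 80 14  8 11 12 11  9 75 78 14 84 74 16 76 17 12 15 ]
T [ 75  8  7 12 14 10 12 12 11 12 11 10  6 12 12 11 12 70 15 ]
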