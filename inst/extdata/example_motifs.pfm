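>MOTIF_A
A [ 12  2  0 14  1  0  3  9 ]
C [  1  1  0  0 13  0  2  2 ]
G [  2 11  1  1  0 14  8  2 ]
T [  0  1 14  0  1  1  2  2 ]
>MOTIF_B
A [  0  9  1  0  2 11  0  1  4 ]
C [ 13  2  2  0 10  1  1  1  5 ]
G [  1  1  1 14  1  2  0 12  3 ]
T [  1  3 11  1  2  1 14  1  3 ]
>MOTIF_C
A [  5  0 15  1  0  0  2 ]
C [  4  0  0 13  1  2  6 ]
G [  3 15  0  1  0 11  4 ]
T [  3  0  0  0 14  2  3 ]
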