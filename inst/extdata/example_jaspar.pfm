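>MA0004.1 Arnt
A  [ 4 19  0  0  0  0 ]
C  [16  0 20  0  0  0 ]
G  [ 0  1  0 20  0 20 ]
T  [ 0  0  0  0 20  0 ]
>MA0006.1 Ahr::Arnt
A  [ 3  0  0  0  0  0 ]
C  [ 8  0 23  0  0  0 ]
G  [ 2 23  0 23  0 24 ]
T  [11  1  1  1 24  0 ]
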