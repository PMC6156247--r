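>GAS_synthetic synthetic GAS-class matrix (consensus TTCCGGGAA)
A [  1  1  1  1  1  1  1 98 98 ]
C [  1  1 98 98  1  1  1  1  1 ]
G [  0  0  1  1 98 98 98  1  1 ]
T [ 98 98  0  0  0  0  0  0  0 ]
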