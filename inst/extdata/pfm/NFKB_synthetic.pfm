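>NFKB_synthetic synthetic NF-kB-class matrix (consensus GGGACTTTCC)
A [  1  1  1 98  1  1  1  1  1  1 ]
C [  1  1  1  1 98  1  1  1 98 98 ]
G [ 98 98 98  1  1  0  0  0  1  1 ]
T [  0  0  0  0  0 98 98 98  0  0 ]
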