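9
EtOH anti conformer, standard all-atom bond parameters (synthetic reference geometry)
C   0.0000  0.0000  0.0000
C   1.5290  0.0000  0.0000
O   1.9647  1.3410  0.0000
H   2.9097  1.3492  0.0000
H   1.9143 -0.5236  0.8749
H   1.9143 -0.5236 -0.8749
H  -0.3853  0.5098 -0.8830
H  -0.3853 -1.0196  0.0000
H  -0.3853  0.5098  0.8830
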