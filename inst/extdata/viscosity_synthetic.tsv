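# SYNTHETIC viscosity table: plausible stand-in values, not measurements.
temperature_K	pct_vol	viscosity_mPas
277	0	1.56
277	3	1.8052
277	6	2.0729
277	9	2.3631
277	12	2.6757
277	15	3.0108
285	0	1.23
285	3	1.4234
285	6	1.6344
285	9	1.8632
285	12	2.1097
285	15	2.3739
293	0	1.002
293	3	1.1595
293	6	1.3315
293	9	1.5178
293	12	1.7186
293	15	1.9339
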