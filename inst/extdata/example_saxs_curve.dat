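# synthetic SAXS curve, q [1/A]  intensity
0.0020 1.3309
0.0035 1.2991
0.0050 1.1275
0.0065 0.9740
0.0080 0.7352
0.0095 0.5400
0.0110 0.3603
0.0125 0.2214
0.0140 0.1216
0.0155 0.0569
0.0170 0.0259
0.0185 0.0133
0.0200 0.0122
0.0215 0.0186
0.0230 0.0242
0.0245 0.0244
0.0260 0.0208
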