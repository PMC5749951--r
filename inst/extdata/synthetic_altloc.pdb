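REMARK synthetic altloc fixture: A/B conformers at 0.6/0.4 and a 0.5/0.5 tie
ATOM      1  N   SER A   5       0.000   0.000   0.000  1.00  0.00
ATOM      2  CA ASER A   5       1.458   0.000   0.000  0.60 10.00
ATOM      3  CA BSER A   5       1.400   0.300   0.000  0.40 12.00
ATOM      4  OG ASER A   5       2.000   1.000   1.000  0.50  8.00
ATOM      5  OG BSER A   5       2.100   1.100   0.900  0.50  9.00
END
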