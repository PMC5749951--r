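REMARK synthetic 3-model fixture with a rigid 1 A x-shift per frame
MODEL        1
ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00
ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00
ATOM      3  C   GLY A   1       2.009   1.421   0.000  1.00  0.00
ENDMDL
MODEL        2
ATOM      1  N   GLY A   1       1.000   0.000   0.000  1.00  0.00
ATOM      2  CA  GLY A   1       2.458   0.000   0.000  1.00  0.00
ATOM      3  C   GLY A   1       3.009   1.421   0.000  1.00  0.00
ENDMDL
MODEL        3
ATOM      1  N   GLY A   1       2.000   0.000   0.000  1.00  0.00
ATOM      2  CA  GLY A   1       3.458   0.000   0.000  1.00  0.00
ATOM      3  C   GLY A   1       4.009   1.421   0.000  1.00  0.00
ENDMDL
END
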