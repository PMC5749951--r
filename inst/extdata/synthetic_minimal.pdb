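REMARK synthetic two-atom fixture (not a deposited structure)
ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00
ATOM      2  CA  ALA A   1      12.560   6.071  -6.351  1.00  0.00
END
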