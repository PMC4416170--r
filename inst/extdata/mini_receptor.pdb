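ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N
ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C
ATOM      3  C   ALA A   1      10.674   6.719  -4.163  1.00  0.00           C
ATOM      4  O   ALA A   1       9.462   6.563  -4.307  1.00  0.00           O
ATOM      5  CB  ALA A   1      11.891   4.623  -4.741  1.00  0.00           C
ATOM      6  H   ALA A   1      10.321   5.668  -6.802  1.00  0.00           H
HETATM    7  O   HOH A  90      13.100   2.000   1.000  1.00  0.00           O
HETATM    8 ZN    ZN A  91       5.000   5.000   5.000  1.00  0.00          ZN
END
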