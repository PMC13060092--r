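ATOM      1  N   GLY A   1       2.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       3.000   0.500   0.000  1.00  0.00           C
ATOM      3  CA  ALA A   2      13.500   0.000   0.000  1.00  0.00           C
ATOM      4  CB  ALA A   2      11.000   0.000   0.000  1.00  0.00           C
ATOM      5  CA  MET A   3      30.000   0.000   0.000  1.00  0.00           C
ATOM      6  H   MET A   3       1.000   0.000   0.000  1.00  0.00           H
ATOM      7  CA  TRP A   4       0.000  40.000   0.000  1.00  0.00           C
HETATM    8 MN    MN A   9       0.000   0.000   0.000  1.00  0.00          MN
END
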