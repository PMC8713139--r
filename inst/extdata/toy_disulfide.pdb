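ATOM      1  N   CYS A   1       1.000   4.200   0.000  1.00  0.00           N
ATOM      2  CA  CYS A   1       0.000   3.300   0.000  1.00  0.00           C
ATOM      3  CB  CYS A   1       0.000   1.800   0.000  1.00  0.00           C
ATOM      4  SG  CYS A   1       0.000   0.000   0.000  1.00  0.00           S
ATOM      5  N   CYS A   2       3.050   4.200   0.000  1.00  0.00           N
ATOM      6  CA  CYS A   2       2.050   3.300   0.000  1.00  0.00           C
ATOM      7  CB  CYS A   2       2.050   1.800   0.000  1.00  0.00           C
ATOM      8  SG  CYS A   2       2.050   0.000   0.000  1.00  0.00           S
HETATM    9  ZN   ZN Z 999       1.025   4.000   0.000  1.00  0.00          ZN
END
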