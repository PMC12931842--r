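HEADER    SYNTHETIC ALPHA-HELICAL C-ALPHA TRACE (GENERATED FIXTURE)
REMARK    Ten C-alpha positions on an ideal helix; not a real structure.
ATOM      1  CA  ALA A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ALA A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      3  CA  ALA A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  ALA A   4       1.150  -1.992   4.500  1.00  0.00           C
ATOM      5  CA  ALA A   5       1.762   1.478   6.000  1.00  0.00           C
ATOM      6  CA  ALA A   6      -1.762   1.478   7.500  1.00  0.00           C
ATOM      7  CA  ALA A   7      -1.150  -1.992   9.000  1.00  0.00           C
ATOM      8  CA  ALA A   8       2.161  -0.787  10.500  1.00  0.00           C
ATOM      9  CA  ALA A   9       0.399   2.265  12.000  1.00  0.00           C
ATOM     10  CA  ALA A  10      -2.300   0.000  13.500  1.00  0.00           C
END
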