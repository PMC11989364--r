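HEADER pocket 1 atoms (synthetic fixture, Fpocket 4 layout)
ATOM      1  CA  TYR B 702      86.512 111.904 110.883  1.00  0.00           C
ATOM      2  OH  TYR B 702      88.104 113.271 112.005  1.00  0.00           O
ATOM      3  CA  SER B 802      85.340 110.522 113.419  1.00  0.00           C
ATOM      4  OG  SER B 802      86.212 109.873 114.300  1.00  0.00           O
ATOM      5  CA  GLN B 975      88.931 112.874 109.127  1.00  0.00           C
ATOM      6  NE2 GLN B 975      90.233 114.016 110.441  1.00  0.00           N
ATOM      7  CA  ASN B 976      87.705 114.381 107.662  1.00  0.00           C
ATOM      8  ND2 ASN B 976      88.914 115.570 108.020  1.00  0.00           N
ATOM      9  CA  ARG B 625      84.118 113.660 112.874  1.00  0.00           C
ATOM     10  CZ  ARG B 625      82.773 114.905 113.962  1.00  0.00           C
ATOM     11  CA  GLN B 973      85.987 115.224 111.030  1.00  0.00           C
ATOM     12  CA  ARG C  41      89.441 110.713 112.668  1.00  0.00           C
ATOM     13  CZ  ARG C  41      90.875 109.440 113.551  1.00  0.00           C
END
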