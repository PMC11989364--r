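HEADER pocket 2 atoms (synthetic fixture, Fpocket 4 layout)
ATOM      1  CA  ARG B 920      98.662 102.845 112.490  1.00  0.00           C
ATOM      2  CZ  ARG B 920      97.310 101.533 113.308  1.00  0.00           C
ATOM      3  CA  GLU B 970      99.980 104.874 114.116  1.00  0.00           C
ATOM      4  CD  GLU B 970     101.233 105.992 114.980  1.00  0.00           C
ATOM      5  CA  ARG B 625      84.118 113.660 112.874  1.00  0.00           C
ATOM      6  CA  GLN B 973      85.987 115.224 111.030  1.00  0.00           C
ATOM      7  CA  ARG C  41      89.441 110.713 112.668  1.00  0.00           C
ATOM      8  CA  GLU B 966     100.514 103.112 115.772  1.00  0.00           C
END
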