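HETATM    1  FE  HEM A 201       0.000   0.000  -0.350  1.00  0.00              
HETATM    2  NA  HEM A 201       1.000   0.000   0.000  1.00  0.00              
HETATM    3  NB  HEM A 201       0.000   1.000   0.000  1.00  0.00              
HETATM    4  NC  HEM A 201      -1.000   0.000   0.000  1.00  0.00              
HETATM    5  ND  HEM A 201       0.000  -1.000   0.000  1.00  0.00              
ATOM      6  NE2 HIS A  58       0.000   0.000   4.200  1.00  0.00              
ATOM      7  CA  HIS A  58       1.000   1.000   5.000  1.00  0.00              
ATOM      8  CB  HIS A  58       2.000   1.500   5.500  1.00  0.00              
ATOM      9  NE2 HIS A  88       0.000   0.000  -2.500  1.00  0.00              
ATOM     10  CA  HIS A  88       1.000  -1.000  -3.000  1.00  0.00              
ATOM     11  CB  HIS A  88       2.000  -1.500  -3.500  1.00  0.00              
END   
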