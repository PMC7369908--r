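REMARK   1 SYNTHETIC TOY CU SITE, NOT A DEPOSITED STRUCTURE
ATOM      1  NE2 HIS A 101       2.050   0.000   0.000  1.00  0.00           N
ATOM      2  NE2 HIS A 102       0.000   2.100   0.000  1.00  0.00           N
ATOM      3  NE2 HIS A 103       0.000   0.000   2.300  1.00  0.00           N
HETATM    4  O   HOH A 104      -2.100   0.000   0.000  1.00  0.00           O
HETATM    5  O   HOH A 105       0.000  -2.120   0.000  1.00  0.00           O
HETATM    6  O   HOH A 106       0.000   0.000  -2.280  1.00  0.00           O
HETATM    7 CU    CU A 107       0.000   0.000   0.000  1.00  0.00          CU
END
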