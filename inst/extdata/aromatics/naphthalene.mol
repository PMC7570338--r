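naphthalene
  molcolor

 10 11  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7320    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7320   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7320    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7320   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8660   -1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  4  0  0  0  0
  1  3  4  0  0  0  0
  3  4  4  0  0  0  0
  4  5  4  0  0  0  0
  5  6  4  0  0  0  0
  6  2  4  0  0  0  0
  1  7  4  0  0  0  0
  7  8  4  0  0  0  0
  8  9  4  0  0  0  0
  9 10  4  0  0  0  0
 10  2  4  0  0  0  0
M  END
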