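@<TRIPOS>MOLECULE
lig1
 3 2 1
SMALL
NO_CHARGES
@<TRIPOS>ATOM
      1 C1          1.0000    2.0000    3.0000 C.3     1  LIG1        0.0000
      2 N1          2.0000    2.0000    3.0000 N.ar    1  LIG1        0.0000
      3 H1          2.5000    2.5000    3.0000 H       1  LIG1        0.0000
@<TRIPOS>BOND
     1    1    2 1
     2    2    3 1
@<TRIPOS>MOLECULE
lig2
 2 1 1
SMALL
NO_CHARGES
@<TRIPOS>ATOM
      1 C1          1.5000    2.0000    3.0000 C.3     1  LIG2        0.0000
      2 O1          2.5000    2.0000    3.0000 O.2     1  LIG2        0.0000
@<TRIPOS>BOND
     1    1    2 1
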