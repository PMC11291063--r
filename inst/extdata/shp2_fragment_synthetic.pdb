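MODEL        1
ATOM      1  NH1 ARG A 111       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  NH2 ARG A 111      -1.200   1.000   0.300  1.00  0.00           N
ATOM      3  CA  HIS A 114       5.000   2.000   1.000  1.00  0.00           C
ATOM      4  O   LEU A 216       6.500   4.000   2.000  1.00  0.00           O
ATOM      5  N   THR A 218       8.000   3.000   0.000  1.00  0.00           N
ATOM      6  CA  THR A 218       9.400   3.400   0.400  1.00  0.00           C
ATOM      7  C   THR A 218      10.300   2.300   1.100  1.00  0.00           C
ATOM      8  N   GLY A 219      11.600   2.600   1.300  1.00  0.00           N
ATOM      9  OE1 GLU A 249       3.000   0.500   0.800  1.00  0.00           O
ATOM     10  OE2 GLU A 249       3.800   1.600   1.500  1.00  0.00           O
ATOM     11  OE1 GLU A 250       2.000  -2.500   1.000  1.00  0.00           O
ATOM     12  OE2 GLU A 250       3.000  -3.500   1.800  1.00  0.00           O
ATOM     13  CZ3 TRP A 423      20.000  10.000   5.000  1.00  0.00           C
ATOM     14  CG  PRO A 424      22.500  11.000   5.500  1.00  0.00           C
ATOM     15  CA  ASP A 425      24.000  12.000   6.000  1.00  0.00           C
ATOM     16  O   VAL A 428      23.500  14.500   7.000  1.00  0.00           O
ATOM     17  CG  PRO A 429      23.800   9.500   4.200  1.00  0.00           C
ATOM     18  CA  CYS A 459      32.000  20.000  11.000  1.00  0.00           C
ATOM     19  N   PHE A 469      18.000   8.000   3.000  1.00  0.00           N
ATOM     20  CA  PHE A 469      19.200   8.800   3.500  1.00  0.00           C
ATOM     21  CB  PHE A 469      20.100   8.100   4.500  1.00  0.00           C
ATOM     22  CG  PHE A 469      21.300   8.900   5.000  1.00  0.00           C
ENDMDL
MODEL        2
ATOM      1  NH1 ARG A 111       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  NH2 ARG A 111      -1.200   1.000   0.300  1.00  0.00           N
ATOM      3  CA  HIS A 114       5.000   2.000   1.000  1.00  0.00           C
ATOM      4  O   LEU A 216       6.500   4.000   2.000  1.00  0.00           O
ATOM      5  N   THR A 218       8.000   3.000   0.000  1.00  0.00           N
ATOM      6  CA  THR A 218       9.400   3.400   0.400  1.00  0.00           C
ATOM      7  C   THR A 218      10.300   2.300   1.100  1.00  0.00           C
ATOM      8  N   GLY A 219      11.600   2.600   1.300  1.00  0.00           N
ATOM      9  OE1 GLU A 249       7.000   3.500   2.800  1.00  0.00           O
ATOM     10  OE2 GLU A 249       7.800   4.600   3.500  1.00  0.00           O
ATOM     11  OE1 GLU A 250       5.000  -6.500   3.000  1.00  0.00           O
ATOM     12  OE2 GLU A 250       6.000  -7.500   3.800  1.00  0.00           O
ATOM     13  CZ3 TRP A 423      20.000  10.000   5.000  1.00  0.00           C
ATOM     14  CG  PRO A 424      22.500  11.000   5.500  1.00  0.00           C
ATOM     15  CA  ASP A 425      24.000  12.000   6.000  1.00  0.00           C
ATOM     16  O   VAL A 428      23.500  14.500   7.000  1.00  0.00           O
ATOM     17  CG  PRO A 429      23.800   9.500   4.200  1.00  0.00           C
ATOM     18  CA  CYS A 459      28.000  16.000   8.500  1.00  0.00           C
ATOM     19  N   PHE A 469      18.000   8.000   3.000  1.00  0.00           N
ATOM     20  CA  PHE A 469      19.200   8.800   3.500  1.00  0.00           C
ATOM     21  CB  PHE A 469      20.100   8.100   4.500  1.00  0.00           C
ATOM     22  CG  PHE A 469      20.500  10.100   5.600  1.00  0.00           C
ENDMDL
END
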