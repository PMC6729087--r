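REMARK  synthetic engine-output fixture (generated by this package, not a real docking run)
MODEL 1
REMARK VINA RESULT:      -6.1      0.000      0.000
ROOT
ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C 
ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C 
ENDROOT
BRANCH   2   3
ATOM      3  C3  LIG A   1       2.000   1.161   0.808  1.00  0.00     0.000 C 
ATOM      4  O6  LIG A   1       1.525   2.442   0.189  1.00  0.00     0.000 O 
ENDBRANCH   2   3
BRANCH   2   5
ATOM      5  C4  LIG A   1       2.000  -1.275   0.613  1.00  0.00     0.000 C 
ATOM      6  C5  LIG A   1       1.579  -1.337   2.051  1.00  0.00     0.000 C 
ENDBRANCH   2   5
TORSDOF 2
ENDMDL
MODEL 2
REMARK VINA RESULT:      -5.8      0.000      0.000
ROOT
ATOM      1  C1  LIG A   1       0.500   0.000   0.000  1.00  0.00     0.000 C 
ATOM      2  C2  LIG A   1       2.000   0.000   0.000  1.00  0.00     0.000 C 
ENDROOT
BRANCH   2   3
ATOM      3  C3  LIG A   1       2.500   1.161   0.808  1.00  0.00     0.000 C 
ATOM      4  O6  LIG A   1       2.025   2.442   0.189  1.00  0.00     0.000 O 
ENDBRANCH   2   3
BRANCH   2   5
ATOM      5  C4  LIG A   1       2.500  -1.275   0.613  1.00  0.00     0.000 C 
ATOM      6  C5  LIG A   1       2.079  -1.337   2.051  1.00  0.00     0.000 C 
ENDBRANCH   2   5
TORSDOF 2
ENDMDL
MODEL 3
REMARK VINA RESULT:      -5.2      0.000      0.000
ROOT
ATOM      1  C1  LIG A   1       1.000   0.000   0.000  1.00  0.00     0.000 C 
ATOM      2  C2  LIG A   1       2.500   0.000   0.000  1.00  0.00     0.000 C 
ENDROOT
BRANCH   2   3
ATOM      3  C3  LIG A   1       3.000   1.161   0.808  1.00  0.00     0.000 C 
ATOM      4  O6  LIG A   1       2.525   2.442   0.189  1.00  0.00     0.000 O 
ENDBRANCH   2   3
BRANCH   2   5
ATOM      5  C4  LIG A   1       3.000  -1.275   0.613  1.00  0.00     0.000 C 
ATOM      6  C5  LIG A   1       2.579  -1.337   2.051  1.00  0.00     0.000 C 
ENDBRANCH   2   5
TORSDOF 2
ENDMDL
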