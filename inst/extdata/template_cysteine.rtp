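; synthetic toy template: free (reduced) cysteine, thiol hydrogen HG1
; charges are illustrative, chosen to sum to the declared formal charge
[ meta ]
name CYS
formal_charge 0.0
[ atoms ]
; name  type  charge  mass
N    NH1  -0.30  14.007
CA   CT1   0.07  12.011
CB   CT2  -0.11  12.011
SG   S    -0.23  32.060
HG1  HS    0.16   1.008
C    C     0.41  12.011
[ bonds ]
N CA
CA CB
CA C
CB SG
SG HG1
[ angles ]
N CA CB
N CA C
CA CB SG
CB SG HG1
[ dihedrals ]
N CA CB SG
CA CB SG HG1
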