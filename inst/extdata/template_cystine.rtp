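; synthetic toy template: disulfide-bonded half-cystine (no thiol hydrogen)
; the S1-S2 bond itself is an inter-residue term, not part of the template
[ meta ]
name CYS2
formal_charge 0.0
[ atoms ]
; name  type  charge  mass
N    NH1  -0.30  14.007
CA   CT1   0.07  12.011
CB   CT2  -0.10  12.011
SG   SM   -0.08  32.060
C    C     0.41  12.011
[ bonds ]
N CA
CA CB
CA C
CB SG
[ angles ]
N CA CB
N CA C
CA CB SG
[ dihedrals ]
N CA CB SG
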