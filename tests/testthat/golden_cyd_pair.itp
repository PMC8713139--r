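; redoxbond perturbed topology, dialect v1
; per-atom columns: name kind anchor typeA chargeA massA typeB chargeB massB
; per-term trailing flag: A (lambda=0 only), B (lambda=1 only), AB (both)
[ residue 1 ]
name CYD
state_a CYS2
state_b CYS
thiol HG1
sulfur SG
cb CB
formal_charge_a 0
formal_charge_b 0
[ atoms ]
N real - NH1 -0.29999999999999999 14.007 NH1 -0.29999999999999999 14.007
CA real - CT1 0.070000000000000007 12.010999999999999 CT1 0.070000000000000007 12.010999999999999
CB real - CT2 -0.10000000000000001 12.010999999999999 CT2 -0.11 12.010999999999999
SG real - SM -0.080000000000000002 32.060000000000002 S -0.23000000000000001 32.060000000000002
HUD dummy - DUM 0 1.008 HS 0.16 1.008
C real - C 0.40999999999999998 12.010999999999999 C 0.40999999999999998 12.010999999999999
VC vsite CB VST 0 0 VST 0 0
VS vsite SG VST 0 0 VST 0 0
[ bonds ]
N CA AB
CA CB AB
CA C AB
CB SG AB
SG HUD B
[ angles ]
N CA CB AB
N CA C AB
CA CB SG AB
CB SG HUD B
[ dihedrals ]
N CA CB SG AB
CA CB SG HUD B
[ constraints ]
VC = CB
VS = SG
[ residue 2 ]
name CYD
state_a CYS2
state_b CYS
thiol HG1
sulfur SG
cb CB
formal_charge_a 0
formal_charge_b 0
[ atoms ]
N real - NH1 -0.29999999999999999 14.007 NH1 -0.29999999999999999 14.007
CA real - CT1 0.070000000000000007 12.010999999999999 CT1 0.070000000000000007 12.010999999999999
CB real - CT2 -0.10000000000000001 12.010999999999999 CT2 -0.11 12.010999999999999
SG real - SM -0.080000000000000002 32.060000000000002 S -0.23000000000000001 32.060000000000002
HUD dummy - DUM 0 1.008 HS 0.16 1.008
C real - C 0.40999999999999998 12.010999999999999 C 0.40999999999999998 12.010999999999999
VC vsite CB VST 0 0 VST 0 0
VS vsite SG VST 0 0 VST 0 0
[ bonds ]
N CA AB
CA CB AB
CA C AB
CB SG AB
SG HUD B
[ angles ]
N CA CB AB
N CA C AB
CA CB SG AB
CB SG HUD B
[ dihedrals ]
N CA CB SG AB
CA CB SG HUD B
[ constraints ]
VC = CB
VS = SG
[ cross 1 2 ]
[ bond ]
1:SG 2:SG A
[ angles ]
1:CB 1:SG 2:SG A
2:CB 2:SG 1:SG A
[ dihedrals ]
1:CB 1:SG 2:SG 2:CB A
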