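# Dreiding-form generic parameter set, 12-6 nonbonded variant, version 1
#
# Energy forms:
#   bond      U = kb (r - r0)^2            kb kcal/mol/A^2, r0 A
#   angle     U = kv (th - th0)^2          kv kcal/mol/rad^2, th0 deg
#   dihedral  U = 0.5 [A1(1+cos t) + A2(1-cos 2t) + A3(1+cos 3t)]
#   nonbond   U = A/r^12 - C/r^6 with A = D0 R0^12, C = 2 D0 R0^6
#
# vdw rows: type R0(A) D0(kcal/mol). Harmonic constants follow the generic
# single-bond/sp3 Dreiding values (E = 0.5*700*(r-r0)^2 and
# E = 0.5*100*(th-th0)^2, rewritten without the leading 1/2). Torsion rows
# give the total sp3-sp3 barrier about the central bond; it is divided by
# the number of paths when assigned to individual dihedrals.
version 1
vdw C  3.8983 0.0951
vdw H  3.1950 0.0152
vdw HO 3.1950 0.0152
vdw O  3.4046 0.0957
vdw N  3.6621 0.0774
vdw P  4.1500 0.3200
bond C-C 350 1.526
bond C-O 350 1.420
bond C-H 350 1.090
bond H-O 350 0.980
angle C 50 109.471
angle O 50 104.510
dihedral C-C 2.0
dihedral C-O 2.0
hbond depth 4.0
hbond r0 1.95
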