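# Printed complexity measures for the 15 non-trivial colloid functions
# (the canonical input for the cross-measure regression statistics).
# arity is the comparison-group arity used for the LZ/n normalisation;
# f11 is grouped with the two-argument functions. Two typographically
# ambiguous rows are stored under the reading consistent with E = H/D
# and with the published regression lines: f20 (D=0.32, E=3.4) and
# f37 (D=0.1, E=12.0).
id,arity,LZ,LZ_per_n,H,S,D,E
f2,2,4,2,0.1,0.02,0.98,0.1
f11,2,9,4.5,0.07,0.02,0.98,0.1
f3,2,14,7,0.05,0.03,0.1,0.5
f4,2,14,7,0.05,0.03,0.1,0.5
f1,2,16,8,0.5,0.2,0.9,0.6
f7,2,57,28.5,1.9,0.8,0.4,4.8
f8,2,61,30.5,1.9,0.8,0.5,3.8
f12,4,11,2.75,1.4,0.7,0.6,2.3
f14,4,12,3,1.1,0.6,0.5,2.2
f19,4,22,5.5,0.7,0.5,0.5,1.4
f20,4,42,10.5,1.1,0.7,0.32,3.4
f40,4,9,4.5,0.7,0.5,0.5,1.4
f37,8,11,1.375,1.2,0.7,0.1,12.0
f36,8,36,4.5,1.1,0.5,0.5,2.2
f21,8,65,8.125,1.9,0.8,0.5,3.8
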