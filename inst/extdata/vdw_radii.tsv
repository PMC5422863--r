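# Van der Waals radii (Angstrom), Bondi-type set used for SASA
H	1.20
C	1.70
N	1.55
O	1.52
P	1.80
S	1.80
ZN	1.39
MG	1.73
CL	1.75
K	2.75
F	1.47
BR	1.85
FE	1.50
MN	1.50
CA	2.31
NA	2.27
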