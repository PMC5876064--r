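TRIO1	F1	0	0	1	2	2
TRIO1	M1	0	0	2	1	1
TRIO1	C1	F1	M1	1	2	2
SIB1	F2	0	0	1	2	2
SIB1	M2	0	0	2	1	1
SIB1	C2	F2	M2	1	2	2
SIB1	C3	F2	M2	2	2	2
SIB1	C4	F2	M2	1	1	0
SKIP1	G1	0	0	1	2	2
SKIP1	G2	0	0	2	1	1
SKIP1	P1	G1	G2	2	1	2
SKIP1	P2	0	0	1	1	0
SKIP1	C5	P2	P1	1	2	2
NONSEG1	F3	0	0	1	2	2
NONSEG1	M3	0	0	2	1	1
NONSEG1	C6	F3	M3	1	2	1
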