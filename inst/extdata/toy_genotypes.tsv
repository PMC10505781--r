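animal	snp1	snp2	snp3	snp4	snp5	snp6
G1	0	0	0	NA	NA	0
G2	1	0	0	NA	1	0
G3	2	0	0	NA	2	1
G4	1	0	0	1	1	0
G5	0	0	0	0	0	1
G6	2	1	0	2	2	0
G7	1	0	0	1	1	0
G8	1	0	0	1	1	1
G9	0	0	0	0	0	0
G10	2	0	0	2	2	0
G11	1	0	0	1	1	2
G12	0	0	0	0	0	1
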