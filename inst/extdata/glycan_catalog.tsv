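name	hex	hexnac	neuac	dhex	series	note
GM3	2	0	1	0	ganglio
GM2	2	1	1	0	ganglio
GM1	3	1	1	0	ganglio
GD1a	3	1	2	0	ganglio
MSGb5	4	1	1	0	globo
DSGb5	4	1	2	0	globo
DSLc4	3	1	2	0	lacto
GalNAcDSLc4	3	2	2	0	lacto
DUPAN-2	3	1	1	0	lacto	assumed: sialyl-Lc4 antigen composition from standard references
CA19-9	3	1	1	1	lacto	assumed: sialyl-Lewis-a antigen composition from standard references
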