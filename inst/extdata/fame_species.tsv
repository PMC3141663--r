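name	carbons	double_bonds	variant_offset
C12:0	12	0	0
C14:0	14	0	0
C14:1_a	14	1	0
C14:1_b	14	1	6
C16:0	16	0	0
C16:1 (n-6)	16	1	0
C16:1 (n-9)	16	1	6
C17:0	17	0	0
C18:0	18	0	0
C18:1 (n-9)	18	1	0
C18:1_c	18	1	6
C18:2_a	18	2	0
C18:2_b	18	2	6
C18:2_c	18	2	12
C18:2_d	18	2	18
C18:2_e	18	2	24
C20:1_b	20	1	6
C20:2_a	20	2	0
C20:2_b	20	2	6
C20:3_a	20	3	0
C20:3_b	20	3	6
C20:4 (AA)	20	4	0
C22:2	22	2	0
C22:3_a	22	3	0
C22:6 (DHA)	22	6	0
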