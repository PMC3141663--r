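signal	assignment	shifts_ppm	quant_ppm
1	Leucine	0.96	0.96
2	Isoleucine	0.96;1.05	1.05
3	Valine	1.01;1.04	1.01
4	Threonine	1.32	1.32
5	Lactate	1.33	1.33
6	Alanine	1.48	1.48
7	N-acetyl-aspartate	2.00;2.48	2.00
8	Glutamate	2.08;2.34	2.34
9	Glutamine	2.12;2.44;3.76	2.44
10	Oxidized glutathione	2.18;2.57;2.98;3.31;3.78	3.31
11	Reduced glutathione	2.18;2.57;2.98;3.78;4.58	4.58
12	Aspartate	2.80	2.80
13	Citrate	2.55;2.67	2.67
14	Creatine/Phosphocreatine	3.04;3.93	3.04
15	Choline derivatives	3.23	3.23
16	Taurine	3.26;3.41	3.41
17	Glycine	3.56	3.56
18	Serine	3.83;3.98	3.83
19	AXP nucleotides	6.10;6.14;8.20;8.52;8.58	8.52
20	UXP nucleotides	5.97;7.95;8.09	8.09
21	NAD(P)(H)	6.105;8.16;8.835;9.22	9.22
22	Tyrosine	6.99;7.20	7.20
23	Formate	8.46	8.46
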