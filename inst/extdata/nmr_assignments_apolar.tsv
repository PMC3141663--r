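signal	lo_ppm	hi_ppm	center_ppm	assignment	species
1	0.665	0.695	0.680	Total cholesterol C18-H3	cholesterol_total
2	0.840	0.875	0.855	Total cholesterol C26-H3/C27-H3	cholesterol_total
3	0.860	0.910	0.885	Acyl groups CH3 (all except n-3)	acyl_ch3
4	0.905	0.935	0.920	Total cholesterol C21-H3	cholesterol_total
5	0.965	0.995	0.980	n-3 acyl groups CH3	acyl_n3_ch3
6	0.995	1.015	1.005	Free cholesterol C19-H3	cholesterol_free
7	1.015	1.035	1.025	Esterified cholesterol C19-H3	cholesterol_ester
8	1.060	1.190	1.125	Multiple cholesterol protons	cholesterol_total
9	1.200	1.380	1.290	Acyl groups -(CH2)n-	acyl_ch2
10	1.500	1.650	1.575	Acyl groups -OCO-CH2-CH2- and H2O	acyl_oco_ch2
11	1.790	1.880	1.835	Multiple cholesterol protons	cholesterol_total
12	1.970	2.100	2.035	Acyl groups -CH2-CH=CH- (allylic)	acyl_allylic
13	2.240	2.380	2.310	Acyl groups -OCO-CH2-	acyl_oco
14	2.720	2.880	2.800	Acyl groups =HC-CH2-CH= (bis-allylic PUFA)	pufa_bisallylic
15	3.280	3.380	3.330	Choline N(CH3)3	choline
16	3.900	4.020	3.960	Glycerophospholipids N-CH2	phospholipid
17	4.100	4.320	4.210	Glycerol backbone -CH2OCOR (triglyceride)	triglyceride
18	4.330	4.430	4.380	Phosphatidylcholine PO-CH2	phospholipid
19	4.500	4.660	4.580	Esterified cholesterol C3-H	cholesterol_ester
20	5.170	5.240	5.205	Glycerophospholipid backbone >CHOCOR	phospholipid
21	5.240	5.280	5.260	Glycerol backbone >CHOCOR (triglyceride)	triglyceride
22	5.290	5.430	5.360	Acyl groups -CH=CH- (olefinic)	acyl_olefinic
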