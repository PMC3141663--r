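name	parent_mz	formula	adduct	deviation_mda	fragments	verified
Proline	116.07046	C5H9NO2	M+H	-0.145	70.0649;86.0961	TRUE
Leucine/Isoleucine	132.10191	C6H13NO2	M+H	0.005	69.0696;72.0805	TRUE
Spermidine	146.16503	C7H19N3	M+H	-0.144	112.1117;158.0443	TRUE
N-acetyl-aspartate	176.05542	C6H9NO5	M+H	0.091	134.0444;88.0390;165.0542	FALSE
Tyrosine	182.08118	C9H11NO3	M+H	0.010	136.0754;119.0489;72.0806	TRUE
Acetyl spermidine	188.17580	C9H21N3O	M+H	0.061	171.1487;188.0702	TRUE
L-tryptophan	205.09717	C11H12N2O2	M+H	0.016	146.0597;118.0648;193.0339	TRUE
Citric acid	210.06060	C6H8O7	M+NH4	0.002	175.0233;129.0179;173.0804	FALSE
Propionylcarnitine	218.13869	C10H19NO4	M+H	0.005	155.0699;202.1070	TRUE
Pantothenic acid	220.11792	C9H17NO5	M+H	-0.029	184.0963;90.0547;100.0754	TRUE
Unknown 230.18622	230.18622	C11H24O2N3	M+H	-0.084	183.1121;213.1520;173.0802	FALSE
Butyrylcarnitine	232.15416	C11H21NO4	M+H	-0.175	85.0281	TRUE
Unknown 250.03784	250.03784	C6H12O3N4P2	M+H	-0.075		FALSE
Unknown 258.11020	258.11020	C8H20O6NP	M+H	0.100	104.1067;179.0414;162.0216	FALSE
Glutathione reduced	308.09103	C10H17N3O6S	M+H	-0.052	144.0110;116.0161	TRUE
UMP	325.04318	C9H13N2O9P	M+H	0.037	97.0281	TRUE
AMP	348.07036	C10H14N5O7P	M+H	0.001	136.0615;119.0349;296.0650	FALSE
Unknown 425.10794	425.10794			 	350.0753	FALSE
UDP-N-acetyl-hexosamine	608.08866	C17H27N3O17P2	M+H	-0.186	405.0079;204.0861	TRUE
Glutathione oxidized	613.15906	C20H32N6O12S2	M+H	-0.178		FALSE
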