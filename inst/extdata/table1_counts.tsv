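category	row	A_balsamea	L_laricina	P_glauca	P_mariana	P_banksiana	P_strobus	T_occidentalis
CNL	NB_CNL-(LRR)	65	146	115	166	82	103	51
CNL2	NB_CNL2-(LRR)	47	18	17	17	36	21	34
RNL	RPW8	5	5	6	13	8	12	3
RNL	NB_RNL-(LRR)	11	8	6	14	21	12	13
RNL	RPW8-NB_RNL-(LRR)	16	33	19	16	26	16	15
TNL	TIR	43	100	121	144	94	89	72
TNL	NB_TNL-(LRR)	52	97	99	128	104	122	91
TNL	TIR-NB_TNL-(LRR)	55	143	58	105	52	126	154
TNL	TIR-LRR	0	3	1	2	0	2	0
ATYPICAL	Atypical	15	26	8	14	7	14	14
UNDETERMINED	Undetermined	29	54	56	106	56	43	39
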