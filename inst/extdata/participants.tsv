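id	age	seizure_focus	bmi	palatable_rating	preferred_palatable	frontal_operculum	ant_insula	pos_insula
S1	59	Bitemporal	26	5	yes	2(L) 2(R)	6(L) 5(R)	1(L) 2(R)
S2	34	L. Lateral Temporal	32	3	yes	0	9(L)	0
S3	24	R. Mesial Temporal	51	3	yes	0	9(R)	6(R)
S4	49	L. Frontal and L. Mes. Temporal	31	8	yes	7(L)	1(L)	7(L)
S5	51	L. Mesial Temporal	27	10	yes	2(L)	9(L) 5(R)	4(L)
S6	20	R. Parietal/Occipital	19	5	yes	0	9(R)	0
S7	27	R. Parietal	24	8	yes	1(L)	7(L)	3(L)
S8	36	Bitemporal	23	7	yes	2(L)	7(L)	6(L)
S9	46	R Mesial Frontal	28	5	yes	4(R)	3(R)	0
S10	29	R Frontal Dysplasia	41	3	yes	2(L) 1(R)	8(L) 4(R)	6(R)
S11	62	No sz, pain mapping	29	10	yes	3(L)	10(L) 6(R)	6(L) 3(R)
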