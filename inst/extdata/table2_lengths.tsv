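entry	gene_id	length	signal
PSSP1	Solyc01g016530	87	-
PSSP2	Solyc01g081360	151	1-29
PSSP3	Solyc01g108380	77	-
PSSP4	Solyc02g069330	180	1-19
PSSP5	Solyc03g058330	108	-
PSSP6	Solyc04g081180	79	-
PSSP7	Solyc05g010200	115	1-25
PSSP8	Solyc06g048400	155	-
PSSP9	Solyc06g075200	81	1-22
PSSP10	Solyc07g062320	79	-
PSSP11	Solyc08g080020	104	1-19
PSSP12	Solyc09g011280	178	1-23
PSSP13	Solyc09g089590	197	-
PSSP14	Solyc11g005500	130	1-26
PSSP15	Solyc11g005540	136	1-16
PSSP16	Solyc11g006840	126	-
PSSP17	Solyc09g025200	72	1-22
PSSP18	Solyc09g056030	82	-
PSSP19	Solyc01g007270	70	-
PSSP20	Solyc01g079560	109	-
PSSP21	Solyc02g032150	147	-
PSSP22	Solyc02g084140	132	-
PSSP23	Solyc03g116410	117	-
PSSP24	Solyc04g025740	148	-
PSSP25	Solyc04g051070	80	-
PSSP26	Solyc04g078240	161	-
PSSP27	Solyc05g013230	118	-
PSSP28	Solyc07g054360	142	-
PSSP29	Solyc08g061120	190	-
PSSP30	Solyc09g073020	50	-
PSSP31	Solyc09g075110	63	-
PSSP32	Solyc10g047720	172	-
PSSP33	Solyc10g055600	51	-
PSSP34	Solyc01g104390	122	1-27
PSSP35	Solyc02g078090	105	1-26
PSSP36	Solyc03g123770	112	-
PSSP37	Solyc03g123970	116	1-17
PSSP38	Solyc04g014750	105	1-32
PSSP39	Solyc05g005240	192	-
PSSP40	Solyc05g010190	138	1-23
PSSP41	Solyc07g032700	120	-
PSSP42	Solyc07g053400	97	-
PSSP43	Solyc09g011290	188	1-24
PSSP44	Solyc09g091300	148	1-23
PSSP45	Solyc11g012650	204	1-28
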