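gene_no	cyp_name	length_aa	heme_start	heme_motif	perf_start	perf_motif	khelix_start	khelix_motif	ortholog_name	ortholog_identity_pct	ortholog_organism
5706	5208A3	523	450	FSTGRRVCVG	421	PERW	366	ETLR	5208A2	54	Mucor
7634	5876A1	451	363	FGFGPRHCPG	337	PERF	282	ECLR	5206A9	32	Mucor
5134	5206V1	400	332	FGWGRRICPG	306	PNRF	263	EVLR	5206J2	41	P. blakesleeanus
5707	5206W1	349	298	FGWGRRICPG	272	PDRF	217	ECLR	5206A3	39	Rhizopus oryzae
5705	5206U3	393	347	FGWGRRICPG	321	PDRF	266	ESLR	5206D1	43	P. blakesleeanus
6050	5206U2	428	353	FGWGRRICPG	327	PDRF	281	ESLR	5206A9	40	Mucor
6049	5206U1	501	440	FGWGRRICPG	414	PDRF	264	EALR	5206Q1	44	Mucor
3940	5313E1	511	447	FSLGSRNCIG	427	PERW	371	ETFR	5313A5	47	Mucor
2620	5313D1	512	446	FSAGSRNCIG	427	PERW	371	ETMR	5313A5	47	Mucor
5881	61A1	496	453	FGSGPRHCIG	434	PDRW	379	EVLR	61A1	80	Rhizopus oryzae
2271	51	512	451	FGAGRRHCIG	412	PYRW	355	ETLR	51	75	P. blakesleeanus
7636	5203A23	498	446	FHAGPRVCLG	425	PERW	375	ESLR	5203	60	Mucor
4152	5203A19	516	455	FHGGPRVCLG	434	PERW	378	EVLR	5203	61	Mucor
4151	5203A18	516	455	FHGGPRVCLG	434	PERW	378	EVLR	5203	60	P. blakesleeanus
4150	5203A17	515	454	FHGGPRFCLG	433	PERW	377	EVLR	5203A13	61	R. oryzae
4156	5203A20	509	448	FHGGPRVCLG	427	PERW	371	EVLR	5203A14	65	Mucor
2735	5203A16	381	318	FHAGPRVCLG	297	PERW	241	ETLR	5203A13	62	Mucor
6919	5203A22	506	446	FHAGPRVCLG	425	PERW	369	EVLR	5203A5	57	R. oryzae
4322	5203A21	526	466	FHAGPRVCLG	445	PERW	372	EVLR	5203A13	59	Mucor
4063	5210C1	580	519	FLYGPRTCIG	500	PDRW	445	ESLR	510A6	51	P. blakesleeanus
2194	5210B1	517	457	FLAGGRQCIG	438	PSRW	383	ESLR	510A6	48	P. blakesleeanus
4598	5205A8	1,211	482	FSTGPRACIG	463	PDRF	408	ETLR	5205A5	62	Mucor
7756	509A1	474	409	FSSGNRQCIG	387	PDRW	331	ETLR	509A1	94	C. elegans
7465	509A4	497	460	FSNGSRQCLG	440	PDRF	384	ETMR	509A1	60	C. elegans
7464	509A5	398	362	FSNGSRQCLG	342	PDRF	286	ETMR	509A1	61	C. elegans
7761	509N1	549	449	FSSGPRMCIG	427	PDRF	371	ETLR	509A1	48	C. elegans
7762	509A3	345	281	FSNGSRQCIG	259	PDRF	219	ETLR	509A1	60	C. elegans
7258	509A2	302	304	FSKGNRQCIG	282	PERF	226	ETLR	509A1	67	C. elegans
6826	509Q1	538	474	FASGSRMCIG	452	PDRF	397	ETLR	509A1	45	P. blakesleeanus
2634	509P1	408	390	FSSGPRICIG	368	PDRF	313	ETLR	509F1	45	P. blakesleeanus
2635	509P2	585	308	FQHGPRVCIG	286	PDRF	231	ETLR	509F1	50	P. blakesleeanus
7342	509M1	453	398	FSSGQRQCVG	369	PERF	314	ENLR	509C9	40	R. oryzae
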