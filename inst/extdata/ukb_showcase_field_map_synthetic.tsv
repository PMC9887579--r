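field_id	name
23400	XXL_VLDL_P
23401	XXL_VLDL_L
23402	XXL_VLDL_PL
23403	XXL_VLDL_C
23404	XXL_VLDL_CE
23405	XXL_VLDL_FC
23406	XXL_VLDL_TG
23407	XL_VLDL_P
23408	XL_VLDL_L
23409	XL_VLDL_PL
23410	XL_VLDL_C
23411	XL_VLDL_CE
23412	XL_VLDL_FC
23413	XL_VLDL_TG
23414	L_VLDL_P
23415	L_VLDL_L
23416	L_VLDL_PL
23417	L_VLDL_C
23418	L_VLDL_CE
23419	L_VLDL_FC
23420	L_VLDL_TG
23421	M_VLDL_P
23422	M_VLDL_L
23423	M_VLDL_PL
23424	M_VLDL_C
23425	M_VLDL_CE
23426	M_VLDL_FC
23427	M_VLDL_TG
23428	S_VLDL_P
23429	S_VLDL_L
23430	S_VLDL_PL
23431	S_VLDL_C
23432	S_VLDL_CE
23433	S_VLDL_FC
23434	S_VLDL_TG
23435	XS_VLDL_P
23436	XS_VLDL_L
23437	XS_VLDL_PL
23438	XS_VLDL_C
23439	XS_VLDL_CE
23440	XS_VLDL_FC
23441	XS_VLDL_TG
23442	IDL_P
23443	IDL_L
23444	IDL_PL
23445	IDL_C
23446	IDL_CE
23447	IDL_FC
23448	IDL_TG
23449	L_LDL_P
23450	L_LDL_L
23451	L_LDL_PL
23452	L_LDL_C
23453	L_LDL_CE
23454	L_LDL_FC
23455	L_LDL_TG
23456	M_LDL_P
23457	M_LDL_L
23458	M_LDL_PL
23459	M_LDL_C
23460	M_LDL_CE
23461	M_LDL_FC
23462	M_LDL_TG
23463	S_LDL_P
23464	S_LDL_L
23465	S_LDL_PL
23466	S_LDL_C
23467	S_LDL_CE
23468	S_LDL_FC
23469	S_LDL_TG
23470	XL_HDL_P
23471	XL_HDL_L
23472	XL_HDL_PL
23473	XL_HDL_C
23474	XL_HDL_CE
23475	XL_HDL_FC
23476	XL_HDL_TG
23477	L_HDL_P
23478	L_HDL_L
23479	L_HDL_PL
23480	L_HDL_C
23481	L_HDL_CE
23482	L_HDL_FC
23483	L_HDL_TG
23484	M_HDL_P
23485	M_HDL_L
23486	M_HDL_PL
23487	M_HDL_C
23488	M_HDL_CE
23489	M_HDL_FC
23490	M_HDL_TG
23491	S_HDL_P
23492	S_HDL_L
23493	S_HDL_PL
23494	S_HDL_C
23495	S_HDL_CE
23496	S_HDL_FC
23497	S_HDL_TG
23498	VLDL_P
23499	LDL_P
23500	HDL_P
23501	Total_P
23502	VLDL_L
23503	LDL_L
23504	HDL_L
23505	Total_L
23506	VLDL_PL
23507	LDL_PL
23508	HDL_PL
23509	Total_PL
23510	VLDL_C
23511	LDL_C
23512	HDL_C
23513	Total_C
23514	VLDL_CE
23515	LDL_CE
23516	HDL_CE
23517	Total_CE
23518	VLDL_FC
23519	LDL_FC
23520	HDL_FC
23521	Total_FC
23522	VLDL_TG
23523	LDL_TG
23524	HDL_TG
23525	Total_TG
23526	non_HDL_C
23527	Remnant_C
23528	Clinical_LDL_C
23529	VLDL_size
23530	LDL_size
23531	HDL_size
23532	Phosphoglyc
23533	Cholines
23534	Phosphatidylc
23535	Sphingomyelins
23536	TG_by_PG
23537	ApoA1
23538	ApoB
23539	ApoB_by_ApoA1
23540	Omega_3
23541	Omega_6
23542	MUFA
23543	SFA
23544	LA
23545	DHA
23546	Unsaturation
23547	PUFA
23548	Total_FA
23549	Omega_3_pct
23550	Omega_6_pct
23551	PUFA_pct
23552	MUFA_pct
23553	SFA_pct
23554	LA_pct
23555	DHA_pct
23556	PUFA_by_MUFA
23557	Omega_6_by_Omega_3
23558	Ala
23559	Gln
23560	Gly
23561	His
23562	Ile
23563	Leu
23564	Val
23565	Phe
23566	Tyr
23567	Total_BCAA
23568	Glucose
23569	Lactate
23570	Pyruvate
23571	Citrate
23572	bOHbutyrate
23573	Acetate
23574	Acetoacetate
23575	Acetone
23576	Creatinine
23577	GlycA
23578	Albumin
23579	XXL_VLDL_PL_pct
23580	XXL_VLDL_C_pct
23581	XXL_VLDL_CE_pct
23582	XXL_VLDL_FC_pct
23583	XXL_VLDL_TG_pct
23584	XL_VLDL_PL_pct
23585	XL_VLDL_C_pct
23586	XL_VLDL_CE_pct
23587	XL_VLDL_FC_pct
23588	XL_VLDL_TG_pct
23589	L_VLDL_PL_pct
23590	L_VLDL_C_pct
23591	L_VLDL_CE_pct
23592	L_VLDL_FC_pct
23593	L_VLDL_TG_pct
23594	M_VLDL_PL_pct
23595	M_VLDL_C_pct
23596	M_VLDL_CE_pct
23597	M_VLDL_FC_pct
23598	M_VLDL_TG_pct
23599	S_VLDL_PL_pct
23600	S_VLDL_C_pct
23601	S_VLDL_CE_pct
23602	S_VLDL_FC_pct
23603	S_VLDL_TG_pct
23604	XS_VLDL_PL_pct
23605	XS_VLDL_C_pct
23606	XS_VLDL_CE_pct
23607	XS_VLDL_FC_pct
23608	XS_VLDL_TG_pct
23609	IDL_PL_pct
23610	IDL_C_pct
23611	IDL_CE_pct
23612	IDL_FC_pct
23613	IDL_TG_pct
23614	L_LDL_PL_pct
23615	L_LDL_C_pct
23616	L_LDL_CE_pct
23617	L_LDL_FC_pct
23618	L_LDL_TG_pct
23619	M_LDL_PL_pct
23620	M_LDL_C_pct
23621	M_LDL_CE_pct
23622	M_LDL_FC_pct
23623	M_LDL_TG_pct
23624	S_LDL_PL_pct
23625	S_LDL_C_pct
23626	S_LDL_CE_pct
23627	S_LDL_FC_pct
23628	S_LDL_TG_pct
23629	XL_HDL_PL_pct
23630	XL_HDL_C_pct
23631	XL_HDL_CE_pct
23632	XL_HDL_FC_pct
23633	XL_HDL_TG_pct
23634	L_HDL_PL_pct
23635	L_HDL_C_pct
23636	L_HDL_CE_pct
23637	L_HDL_FC_pct
23638	L_HDL_TG_pct
23639	M_HDL_PL_pct
23640	M_HDL_C_pct
23641	M_HDL_CE_pct
23642	M_HDL_FC_pct
23643	M_HDL_TG_pct
23644	S_HDL_PL_pct
23645	S_HDL_C_pct
23646	S_HDL_CE_pct
23647	S_HDL_FC_pct
23648	S_HDL_TG_pct
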