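entity_id	lung	brain	liver	heart	kidney	ovary	testis	spleen	thymus	skin
gene01	102	30	551	191	624	258	150	712	760	149
gene02	695	380	709	254	60	370	625	501	836	907
gene03	902	102	65	205	351	238	107	678	900	801
gene04	393	629	572	225	586	358	319	83	767	812
gene05	321	165	324	137	26	191	263	236	273	866
gene06	296	414	156	486	171	970	976	581	532	66
gene07	667	526	78	441	471	456	514	614	591	632
gene08	725	107	324	37	893	665	746	437	459	565
gene09	444	535	100	75	308	335	337	216	514	524
gene10	834	133	812	797	977	586	581	938	761	21
gene11	549	621	104	724	646	597	649	554	609	902
gene12	905	716	829	107	344	934	568	258	547	23
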