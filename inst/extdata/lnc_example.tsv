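chrom	start	end	name	lung	brain	liver	heart	kidney	ovary	testis	spleen
chr1	10000	12500	TCONS_00001	0	0	0	0	0	950	0	0
chr2	50000	52500	TCONS_00002	900	5	0	10	0	0	0	5
chr3	2000	4500	TCONS_00003	632	355	635	244	55	345	566	455
chr3	90000	92500	TCONS_00004	511	261	521	214	59	305	440	385
chr5	400	2900	TCONS_00005	505	516	354	748	51	84	784	360
chr9	7000	9500	TCONS_00006	872	480	137	552	221	427	460	413
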