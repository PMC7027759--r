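variant_id	chrom	pos	risk_allele	other_allele	weight	control_af
grs9_hla_classii_a	6	32605884	A	G	2.00	0.674
grs9_hla_classii_b	6	32713706	C	T	1.80	0.021
grs9_ins_vntr_tag	11	2182224	T	C	1.00	0.648
grs9_ptpn22	1	114377568	A	G	0.80	0.629
grs9_il2ra	10	6094697	C	T	0.65	0.610
grs9_erbb3	12	56482180	G	A	0.55	0.595
grs9_sh2b3	12	111884608	T	C	0.50	0.587
grs9_clec16a	16	11194771	G	A	0.45	0.580
grs9_ctla4	2	204738919	G	A	0.40	0.570
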