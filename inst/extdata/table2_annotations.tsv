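chrom	pos	ref	alt	region_class	maf_1000g	maf_exac	maf_esp6500	maf_gnomad	dbsnp_id	dbsnp_exact_allele_match	clinvar_assertion	cosmic_ids	cosmic_pathogenic
chr19	13054555	AGAGGACGAGGAGGACAAGGACGGCGACGAGGACGAGGACGGCGATGAGGACG	A	exonic	.	.	.	.	.	FALSE	Pathogenic	COSM1738055	TRUE
chr19	13054600	A	ATTGTC	exonic	.	.	.	.	rs765476509	TRUE	absent	COSM1738056	FALSE
chr19	13054599	T	TTATGT	exonic	.	.	.	.	.	FALSE	absent	COSM5985669	FALSE
chr19	13054601	A	C	exonic	.	.	.	.	rs1024435400	TRUE	absent		FALSE
chr9	5073770	G	T	exonic	.	.	.	.	rs77375493	TRUE	Pathogenic	COSM12600	TRUE
chr9	133748283	A	G	exonic	.	.	.	.	rs144448357	TRUE	absent		FALSE
chr20	31022442	G	GGGGGGGGGTGGCCCGGGTGGAGGTGGCGGCGGGGCCACCGATGAGGGGGGGGGCAGAGGCAGCAGCA	exonic	.	.	.	.	rs750318549	FALSE	absent		FALSE
chr20	31021444	A	AA	exonic	.	.	.	.	rs762036456	TRUE	absent	COSM4169775,COSM4169776	FALSE
chr20	31022235	CA	C	exonic	.	.	.	.	.	FALSE	absent		FALSE
chr20	31024610	A	G	exonic	.	.	.	.	.	FALSE	absent		FALSE
chr2	25470562	G	A	exonic	.	.	.	.	rs368009374	TRUE	VUS		FALSE
chr21	36206898	G	T	exonic	.	.	.	.	rs80314254	TRUE	Benign		FALSE
chr2	198266834	A	G	exonic	.	.	.	.	rs559063155	TRUE	Likely pathogenic	COSM84677	TRUE
chr4	106156747	C	T	exonic	.	.	.	.	.	FALSE	absent	COSM5610834,COSM5610835	FALSE
chr4	106158440	T	G	exonic	.	.	.	.	rs147836249	TRUE	absent	COSM87107	FALSE
chr4	106164726	A	G	exonic	.	.	.	.	rs568009712	TRUE	absent		FALSE
chr4	106164877	A	G	exonic	.	.	.	.	.	FALSE	absent		FALSE
chr4	106180775	TG	T	exonic	.	.	.	.	.	FALSE	absent	COSM4383928	FALSE
chr4	106193892	T	A	exonic	.	.	.	.	.	FALSE	absent	COSM97191	TRUE
chr4	106190862	A	G	exonic	.	.	.	.	rs553669299	TRUE	absent		FALSE
chr21	44514777	A	C	exonic	.	.	.	.	rs371246226	TRUE	Likely pathogenic	COSM211534,COSM1318797	TRUE
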