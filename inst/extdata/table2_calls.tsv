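sample_id	chrom	pos	ref	alt	gene	hgvs_c	hgvs_p	consequence	vaf_percent
09	chr19	13054555	AGAGGACGAGGAGGACAAGGACGGCGACGAGGACGAGGACGGCGATGAGGACG	A	CALR	c.1092_1143del	p.Leu367Thrfs*45	Fs del	10.6
02	chr19	13054600	A	ATTGTC	CALR	c.1154_1155insTTGTC	p.Lys385Asnfs*46	Fs ins	15.9
01	chr19	13054599	T	TTATGT	CALR	c.1153_1154insTATGT	p.Lys385Ilefs*46	Fs ins	35.2
01	chr19	13054601	A	C	CALR	c.1154A>C	p.Lys385Thr	nSNV	35.5
07	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	12.1
10	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	12.2
06	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	19.2
08	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	53.7
05	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	66.5
04	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	72.9
03	chr9	5073770	G	T	JAK2	c.1849G>T	p.Val617Phe	nSNV	88
07	chr9	133748283	A	G	ABL1	c.1049A>G	p.Asn350Ser	nSNV	48.8
04	chr20	31022442	G	GGGGGGGGGTGGCCCGGGTGGAGGTGGCGGCGGGGCCACCGATGAGGGGGGGGGCAGAGGCAGCAGCA	ASXL1	c.1927_1928ins67	p.Gly646Trpfs*10	stopgain	31.3
10	chr20	31021444	A	AA	ASXL1	c.1772dupA	p.Tyr591*	stopgain	40.8
09	chr20	31022235	CA	C	ASXL1	c.2190del	p.Leu731Tyrfs*12	Fs del	38.5
03	chr20	31024610	A	G	ASXL1	c.4299A>G	p.Gln1433Gln	sSNV	49.2
03	chr2	25470562	G	A	DNMT3A	c.1155G>A	p.Pro385Pro	sSNV	51.6
08	chr21	36206898	G	T	RUNX1	c.924G>T	p.Gln308His	nSNV	49.6
08	chr2	198266834	A	G	SF3B1	c.2098A>G	p.Lys700Glu	nSNV	45.6
10	chr4	106156747	C	T	TET2	c.911C>T	p.Ala304Val	nSNV	50.1
02	chr4	106158440	T	G	TET2	c.2604T>G	p.Phe868Leu	nSNV	48.7
01	chr4	106164726	A	G	TET2	c.3583A>G	p.Ile1195Val	nSNV	49.6
08	chr4	106164877	A	G	TET2	c.3734A>G	p.Tyr1245Cys	nSNV	44.9
08	chr4	106180775	TG	T	TET2	c.3937del	p.Asp1314Metfs*48	Fs del	46.3
02	chr4	106193892	T	A	TET2	c.4893T>A	p.Tyr1631*	stopgain	1.4
02	chr4	106190862	A	G	TET2	c.4538A>G	p.Glu1513Gly	nSNV	51.6
06	chr21	44514777	A	C	U2AF1	c.470A>C	p.Gln157Pro	nSNV	9.8
10	chr21	44514777	A	C	U2AF1	c.470A>C	p.Gln157Pro	nSNV	42.5
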