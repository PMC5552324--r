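chrom	pos	ref	alt	id	hgvs	gene	cadd_phred	gwava_region	genomiser	spidex_dpsi	maf_1000g	maf_gnomad	proband_af	published_toolset
chr10	1097891	A	C	rs77884406	c.169-2410A>C	VCL	17.55	0.59	0.910891	.	0.019	0.0273	0.03125	CADD,GWAVA,GENOMISER
chr10	1201267	T	C	rs113195070	c.499+367T>C	VCL	16.93	0.6	0.963367	.	0.06	0.0671	0.1875	CADD,GWAVA,GENOMISER
chr15	1000772	T	C	rs28595759	c.129+472T>C	ACTC1	21.9	0.53	0.9792082	.	0.07	0.0604	0.03125	CADD,GWAVA,GENOMISER
chr2	1501872	T	C	rs2243452	c.32929+72T>C	TTN	22.2	0.53	0.939604	0.6211	0.029	0.0247	0.03125	CADD,GWAVA,GENOMISER
chr2	1100163	C	T	rs2253324	c.10361-138C>T	TTN	18.03	0.51	0.825743	3.3164	0.048	0.0441	0.03125	CADD,GWAVA,GENOMISER
chr7	1300584	T	G	rs141541040	c.1234-317T>G	PRKAG2	15.20	0.58	0.872277	.	0.003	0.0010	0.03125	CADD,GWAVA,GENOMISER
chr10	1001465	C	T	rs7079796	c.168+1165C>T	VCL	15.74	0.35	0.812872	.	0.2	0.2191	0.15625	CADD,GENOMISER
chr10	1092729	C	T	.	c.169-7572C>T	VCL	15.88	.	0.905941	.	.	.	0.03125	CADD,GENOMISER
chr10	1104899	C	A	.	c.239+4299C>A	VCL	18.78	.	0.983169	.	.	0.0001	0.0625	CADD,GENOMISER
chr10	3002127	G	A	rs12570315	c.93+1827G>A	LDB3	16.75	0.23	0.858416	.	0.3	0.3436	0.25	CADD,GENOMISER
chr10	3102514	C	T	.	c.548+1914C>T	LDB3	21.4	.	0.970297	.	.	.	0.03125	CADD,GENOMISER
chr10	3102593	C	T	rs779483568	c.548+1993C>T	LDB3	17.35	.	0.990099	.	.	0.0001	0.03125	CADD,GENOMISER
chr12	1000904	C	T	rs2040571	c.3+604C>T	MYL2	15.58	0.36	0.89703	.	0.086	0.0888	0.03125	CADD,GENOMISER
chr7	1155754	T	G	rs62478182	c.467-44847T>G	PRKAG2	17.95	0.26	0.880198	.	0.34	0.3721	0.25	CADD,GENOMISER
chr7	1070059	C	T	rs114394151	c.115-30242C>T	PRKAG2	18.38	0.49	0.925743	.	.	0	0.0625	CADD,GENOMISER
chrX	1097415	A	G	rs5956217	c.1094-2886A>G	LAMP2	15.93	0.42	0.881188	.	0.004	0.0009	0.03125	CADD,GENOMISER
chrX	1097377	C	T	rs42887	c.1094-2924C>T	LAMP2	20.4	0.43	0.929703	.	0.11	0.1711	0.125	CADD,GENOMISER
chr2	1701401	G	A	rs12693162	c.37112-700G>A	TTN	18.66	0.5	0.190099	.	0.22	0.2261	0.21875	CADD,GWAVA
chrX	1200461	A	G	rs141348126	c.1094-140A>G	LAMP2	15.68	0.5	0.545545	.	.	0	0.03125	CADD,GWAVA
chr10	1801964	G	C	rs2131959	c.2132-437G>C	VCL	10.13	0.57	0.89604	.	0.75	0.7445	0.84375	GWAVA,GENOMISER
chr10	5000539	G	T	rs10509614	c.207+239G>T	ANKRD1	13.87	0.52	0.838614	0.7561	0.04	0.0314	0.03125	GWAVA,GENOMISER
chr2	1000617	T	C	rs80259697	c.10360+317T>C	TTN	13.04	0.51	0.821782	.	.	6.68e-05	0.03125	GWAVA,GENOMISER
chr2	1200315	G	T	rs142156368	c.31484-286G>T	TTN	15.63	0.38	0.425	6.092	0.0089	0.0047	0.0625	CADD,SPIDEX
chr2	1301311	A	G	rs2562845	c.32593+111A>G	TTN	3.232	0.29	0	9.1111	0.21	0.2015	0.15625	SPIDEX
chr2	1401531	C	G	rs72650063	c.32077+31C>G	TTN	0.713	0.41	0.019802	5.8489	0.021	0.0218	0.0625	SPIDEX
chr2	1202615	A	C	rs2742353	c.31484+1715A>C	TTN	10.79	0.26	0.556436	6.2975	0.029	0.0247	0.03125	SPIDEX
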