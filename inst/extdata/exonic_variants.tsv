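chrom	pos	ref	alt	id	hgvs	hgvs_p	gene	patient	clinical_class	clinvar
chr1	1100350	G	C	rs727504869	c.198G>C	p.Lys76Asn	TNNT2	P01	VUS	VUS
chr11	1300882	G	A	rs587776699	c.1224-19G>A	.	MYBPC3	P02	VUS	conflicting
chr2	1802450	C	G	rs781121273	c.57478C>G	p.Leu19160Val	TTN	P05	VUS	VUS
chr11	1401188	G	A	rs397515893	c.1227-13G>A	.	MYBPC3	P06	pathogenic	reported
chr15	3000062	G	T	rs730881151	c.62G>T	p.Arg21Leu	TPM1	P07	VUS	conflicting
chr11	1601850	C	T	rs387907267	c.2827C>T	p.Arg943Ter	MYBPC3	P08	pathogenic	reported
chr15	3200641	A	G	rs397516394	c.841A>G	p.Met281Val	TPM1	P12	VUS	VUS
chr14	1100392	G	A	rs140596256	c.292G>A	p.Glu98Lys	MYH6	P14,P16	VUS	VUS
chrX	3000187	T	A	.	c.187T>A	p.Cys63Ser	GLA	P14	VUS	novel
chr11	1401250	G	A	rs200411226	c.1484G>A	p.Arg495Gln	MYBPC3	P15	likely_pathogenic	reported
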