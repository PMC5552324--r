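chr1	1000000	1903000	TNNT2	0	-	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr2	1000000	1903000	TTN	0	+	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr7	1000000	1903000	PRKAG2	0	+	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr10	1000000	1903000	VCL	0	+	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr10	3000000	3903000	LDB3	0	+	3000000	3903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr10	5000000	5903000	ANKRD1	0	+	5000000	5903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr11	1000000	1903000	MYBPC3	0	-	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr12	1000000	1903000	MYL2	0	+	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr14	1000000	1903000	MYH6	0	-	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr15	1000000	1903000	ACTC1	0	+	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chr15	3000000	3903000	TPM1	0	+	3000000	3903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chrX	1000000	1903000	LAMP2	0	-	1000000	1903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
chrX	3000000	3903000	GLA	0	-	3000000	3903000	0	10	300,300,300,300,300,300,300,300,300,300	0,100300,200600,300900,401200,501500,601800,702100,802400,902700
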