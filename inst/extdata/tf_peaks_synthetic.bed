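chr10	1201100	1201400	FOS
chr10	1201150	1201350	JUN
chr10	1201200	1201320	EP300
chr7	1069900	1070200	FOS
chr7	1069950	1070150	JUN
chr2	1500000	1500200	GATA4
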