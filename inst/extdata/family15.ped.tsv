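family	individual	father	mother	sex	phenotype	chr11:1401250:G:A
15	I-1	0	0	male	affected	carrier_het
15	II-1	I-1	0	female	affected	carrier_het
15	III-1	0	II-1	male	affected	carrier_het
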