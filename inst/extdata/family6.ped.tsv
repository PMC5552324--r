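family	individual	father	mother	sex	phenotype	chr11:1401188:G:A	chr10:1201267:T:C
6	I-2	0	0	male	affected	carrier_het	carrier_het
6	II-1	I-2	0	male	affected	carrier_het	carrier_het
6	II-2	I-2	0	female	unaffected	carrier_het	noncarrier
6	II-3	I-2	0	female	unaffected	carrier_het	noncarrier
6	II-4	I-2	0	male	unaffected	noncarrier	noncarrier
6	II-5	I-2	0	female	unaffected	noncarrier	noncarrier
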