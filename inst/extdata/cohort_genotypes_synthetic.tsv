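sample	sex	chr10:1097891:A:C	chr10:1201267:T:C	chr15:1000772:T:C	chr2:1501872:T:C	chr2:1100163:C:T	chr7:1300584:T:G	chr10:1001465:C:T	chr10:1092729:C:T	chr10:1104899:C:A	chr10:3002127:G:A	chr10:3102514:C:T	chr10:3102593:C:T	chr12:1000904:C:T	chr7:1155754:T:G	chr7:1070059:C:T	chrX:1097415:A:G	chrX:1097377:C:T	chr2:1701401:G:A	chrX:1200461:A:G	chr10:1801964:G:C	chr10:5000539:G:T	chr2:1000617:T:C	chr2:1200315:G:T	chr2:1301311:A:G	chr2:1401531:C:G	chr2:1202615:A:C	chr1:1100350:G:C	chr11:1300882:G:A	chr2:1802450:C:G	chr11:1401188:G:A	chr15:3000062:G:T	chr11:1601850:C:T	chr15:3200641:A:G	chr14:1100392:G:A	chrX:3000187:T:A	chr11:1401250:G:A
P01	male	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hemi	het	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P02	male	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	het	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P03	female	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	het	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P04	female	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P05	male	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P06	male	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_alt	het	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P07	male	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P08	male	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref
P09	female	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P10	female	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	het	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P11	female	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_alt	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P12	female	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref
P13	male	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref
P14	female	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	het	het	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	het	hom_ref
P15	female	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	het	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het
P16	male	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	het	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	hom_ref	het	hom_ref	hom_ref
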