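genus	guild	n_CN	n_AUS	extra_CN	extra_AUS	max_intra_CN	max_intra_AUS
Eupristina	pollinator	1	1	0	0	1.2	0.5
Philotrypesis	small_parasitoid	4	3	0	1	19	13
Sycoscapter	small_parasitoid	2	3	0	0	14	3
Sycorycteridea	small_parasitoid	0	1	0	0	NA	2
Walkerella	small_galler	2	2	0	1	17	14
Sycobia	large_galler	1	1	0	0	11	4
Sycophila	large_parasitoid	2	3	0	0	16	18
Acophila	large_galler	1	0	0	0	2	NA
Ormyrus	large_parasitoid	1	0	0	0	NA	NA
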