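# Per-sample summary of a reference coastal-seawater proteomic SIP experiment:
# eight microcosms amended with 13C-labeled dissolved free amino acids at two
# locations (MB: Monterey Bay, three replicates per time point; OR: Oregon
# coast, one sample per time point) and two incubation times (15 h, 32 h).
sample_id	location	incubation_h	n_psm	n_peptides	n_proteins	label_frequency_pct	avg_enrichment_pct
MB1a	MB	15	22208	18631	3378	2.43	14.96
MB1b	MB	15	22669	19800	3613	2.72	16.01
MB1c	MB	15	25157	19668	3513	2.14	15.57
MB2a	MB	32	15959	15170	2885	3.95	20.17
MB2b	MB	32	17928	14992	2772	4.51	24.77
MB2c	MB	32	17510	15675	2860	5.72	39.93
OR1	OR	15	6554	6441	1190	9.22	33.04
OR2	OR	32	6374	6180	1147	10.34	20.76
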