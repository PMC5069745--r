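# Mean cell counts (cells per ml) over the course of the reference
# incubations, at amendment (0 h) and the two sampling time points.
location	t_h	cells_per_ml
MB	0	2.16e6
MB	15	2.33e6
MB	32	2.94e6
OR	0	4.96e5
OR	15	1.48e6
OR	32	1.96e6
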