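library	prefix	plates	sequencer	reads_5p	reads_3p	overlap_contigs	full_inserts
Eye	Dj_aE	000	ABI 3700	918	0	0	0
Head	Dj_aH	000	ABI 3700	6444	3163	689	495
Head	Dj_aH	001-022	ABI 3700	5024	0	0	21
Head	Dj_aH	101-140	ABI 3700	2364	0	0	4
Head	Dj_aH	201-227	ABI 3730xl	8426	0	0	52
Head	Dj_aH	301-327	ABI 3730xl	8366	7107	4516	21
Head	Dj_aH	401-406	ABI 3730xl	2056	0	0	0
Head	Dj_aH	501-530	ABI 3730xl	9462	8191	5888	0
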