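class	n	total_bases	printed_mean	printed_median
contigs	4883	6642939	1360.4	1252
singletons	8284	5919589	701.1	672
all	13167	12562528	940.5	846
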