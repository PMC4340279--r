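layer	type	variant	rawFeatures	keptFeatures
mrna	type2	NA	18756	3604
mrna	type3	BP	18756	10542
mrna	type3	MF	18756	11149
mrna	type3	CC	18756	10678
mrna	type3	Pathway	18756	13603
mrna	type4	BP	18756	2116
mrna	type4	MF	18756	2232
mrna	type4	CC	18756	2135
mrna	type4	Pathway	18756	2808
mirna	type2	NA	819	114
mirna	type3	NA	819	37
mirna	type4	NA	819	8
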