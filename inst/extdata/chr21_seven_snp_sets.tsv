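# Presence/absence base sets at seven validated chromosome-21 SNPs spanning
# the centromere, one line per locus, sets comma-separated per sample.
# Positions for rs74753297 and rs78248586 are the published GRCh37
# coordinates; the other five positions are synthetic placeholders chosen
# only to keep the loci ordered along the chromosome.
rsid	pos	T21	dP	dM1	dM2
rs74753297	9830857	A,G	G	A,G	A,G
rs62218012	10500000	C,T	C,T	C,T	C
rs3119486	16000000	C,T	C,T	C	C,T
rs447807	24000000	C,T	C,T	T	C,T
rs11702254	31000000	A,G	A	A,G	A,G
rs460855	38000000	A,G	G	A,G	A,G
rs78248586	43465959	C,T	C,T	C,T	C
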