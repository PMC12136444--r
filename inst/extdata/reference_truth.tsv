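gene	name	vtype	classification	target_id	chrom	pos_start	pos_end	ref_allele	alt_allele	known_vaf
BRAF	BRAF c.1799T>A (p.V600E)	SNV	positive	RP01	chr7	140753336	140753336	A	T	0.01
EGFR	EGFR c.2235_2249del (p.E746_A750delELREA)	deletion	positive	RP02	chr7	55174772	55174786	GGAATTAAGAGAAGC	-	0.01
EGFR	EGFR c.2240_2257del (p.L747_P753>S)	deletion	positive	RP02	chr7	55174777	55174794	TAAGAGAAGCAACATCTC	-	0.01
EGFR	EGFR c.2573T>G (p.L858R)	SNV	positive	RP03	chr7	55191822	55191822	T	G	0.01
EGFR	EGFR c.2369C>T (p.T790M)	SNV	positive	RP04	chr7	55181378	55181378	C	T	0.01
KRAS	KRAS c.35G>T (p.G12C)	SNV	positive	RP05	chr12	25245351	25245351	C	A	0.01
KRAS	KRAS c.35G>A (p.G12D)	SNV	positive	RP05	chr12	25245350	25245350	C	T	0.01
EGFR	EGFR G719X codon	codon	negative	RP06	chr7	55174014	55174016	GGC	GAC	0
EGFR	EGFR c.2303G>T (p.S768I)	SNV	negative	RP07	chr7	55181312	55181312	G	T	0
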