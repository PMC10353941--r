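sample_id	chrom	pos	ref	alt	gene	protein_change	ref_reads	alt_reads
S1	chr2	25234373	C	T	DNMT3A	p.R882H	72	28
S2	chr4	105235850	G	A	TET2	p.Q810*	193	7
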