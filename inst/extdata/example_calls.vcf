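##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=PCHANGE,Number=1,Type=String,Description="Protein change">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr2	25234373	.	C	T	.	PASS	GENE=DNMT3A;PCHANGE=p.R882H	GT:AD	0/1:72,28	./.:.
chr4	105235850	.	G	A	.	PASS	GENE=TET2;PCHANGE=p.Q810*	GT:AD	./.:.	0/1:193,7
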