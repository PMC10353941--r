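gene	rule	detail
DNMT3A	listed_protein_changes	p.R882H,p.R882C
TET2	any_truncating	.
ASXL1	any_truncating	.
SF3B1	listed_positions	198266834,198267483
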