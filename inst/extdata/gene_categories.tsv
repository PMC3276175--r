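gene_name	category
# editable gene -> category map; unlisted genes fall back to the naming
# heuristic in gene_category()
psbA	photosynthesis
psbB	photosynthesis
psbD	photosynthesis
psbH	photosynthesis
psbI	photosynthesis
psbJ	photosynthesis
psbK	photosynthesis
psbL	photosynthesis
psbF	photosynthesis
psbN	photosynthesis
psbT	photosynthesis
psaA	photosynthesis
psaB	photosynthesis
psaI	photosynthesis
psaJ	photosynthesis
petA	photosynthesis
petB	photosynthesis
petD	photosynthesis
ndhA	photosynthesis
ndhB	photosynthesis
ndhC	photosynthesis
ndhD	photosynthesis
ndhF	photosynthesis
ndhJ	photosynthesis
ndhK	photosynthesis
atpA	photosynthesis
atpB	photosynthesis
atpI	photosynthesis
rbcL	photosynthesis
rpoA	gene_expression
rpoB	gene_expression
rpoC2	gene_expression
rps4	gene_expression
rps11	gene_expression
rps12	gene_expression
rps14	gene_expression
rps16	gene_expression
rps18	gene_expression
rpl2	gene_expression
rpl14	gene_expression
rpl20	gene_expression
rpl33	gene_expression
rpl36	gene_expression
matK	gene_expression
infA	gene_expression
accD	misc_protein
cemA	misc_protein
ccsA	misc_protein
clpP	misc_protein
orf31	misc_protein
ycf1	ycf
ycf2	ycf
ycf3	ycf
ycf5	ycf
ycf6	ycf
ycf9	ycf
ycf10	ycf
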