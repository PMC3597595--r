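# Published polarity-reversal residue pairs from holo/apo comparisons of
# six enzyme systems (holo/apo PDB accessions in column `structures`).
# pd1/pd2: holo and apo EPD of the pair in kT/e; delta_pd as printed in the
# source table (threshold 150 kT/e).
system	structures	res_a	res_b	pd1	pd2	delta_pd
diphtheria_toxin_repressor	1BI3/1BI2	GLU83	HIS79	8.6	-150.7	159.2
diphtheria_toxin_repressor	1BI3/1BI2	ASP88	ARG84	70.6	-117.2	187.8
diphtheria_toxin_repressor	1BI3/1BI2	HIS106	GLU105	435.8	-18.2	454
diphtheria_toxin_repressor	1BI3/1BI2	ASP122	ARG84	19.7	-182.3	202
diphtheria_toxin_repressor	1BI3/1BI2	GLN173	ASN169	571.5	-126.3	697.8
diphtheria_toxin_repressor	1BI3/1BI2	GLU225	ARG114	284.5	-33.6	318.1
hemoglobin_wt	3SDH/4SDH	SER70	HIS69	77.8	-143.2	221
hemoglobin_wt	3SDH/4SDH	ASP89	ASN86	73.9	-79.1	153
hemoglobin_k96r	3UHI/3UHK	GLU95	ARG96	47	-233.9	280.9
hemoglobin_k96r	3UHI/3UHK	THR103	ARG104	85.3	-75.9	161.1
fructose_16_bisphosphatase	1EYK/1CNQ	GLU97	GLU98	95.6	-66.5	162.1
fructose_16_bisphosphatase	1EYK/1CNQ	GLN154	ASN142	44.5	-188.4	232.9
fructose_16_bisphosphatase	1EYK/1CNQ	TYR164	HIS253	217.3	-82.1	299.4
fructose_16_bisphosphatase	1EYK/1CNQ	ASN179	ARG198	19.9	-165.8	185.7
fructose_16_bisphosphatase	1EYK/1CNQ	TYR240	TYR226	61.3	-106.6	168
ketosteroid_isomerase	3IPT/1OPY	HIS110	GLU109	59.4	-94.2	153.6
cuzn_superoxide_dismutase	1HL5/1HL4	GLU77	ARG69	15.3	-267.8	283.1
cuzn_superoxide_dismutase	1HL5/1HL4	HIS120	HIS48	27.7	-138.4	166.1
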