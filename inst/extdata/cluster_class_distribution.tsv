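class	I (maize)	II (adlay)	III (rice)	IV (foxtail millet)	V (wheat)	VI (common oat)	VII (barley)	VIII (broomcorn millet)	IX (sorghum)
AA and derivatives	7	7	36	8	10	4	14	7	8
Alcohols and polyols	3	9	2	6	6	5	2	10	5
Alkaloids	9	4	15	6	6	4	10	4	6
BA and derivatives	0	2	0	3	2	2	3	1	1
Benzoxazinoids	0	6	0	0	2	0	0	0	0
Coumarins and lignans	3	8	1	5	4	0	2	9	7
Flavonoids	35	36	32	34	69	24	22	23	36
HCA derivatives	3	8	7	15	4	2	8	9	3
Lipids	31	3	9	14	16	43	30	20	6
Nucleotides and derivates	8	4	9	3	6	3	5	3	7
Organic acids	2	10	6	9	3	6	3	12	6
Others	4	5	4	2	6	1	4	3	1
Phenolamides	0	7	15	1	2	1	9	11	0
Phenolic acids	3	7	1	7	5	1	1	4	4
Phytohormones	4	6	2	4	3	2	1	2	3
Quinate and derivatives	2	1	2	1	4	2	0	2	2
Terpenoids	0	2	5	5	2	3	6	2	1
Vitamins	1	2	6	7	4	2	4	2	4
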