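# Published counts of small in-frame indels (1-6 aa) used for validation:
# disease-causing indels from a disease-mutation database (hgmd_*) and
# common indels from a population sequencing catalogue (kg_*).
length_aa	hgmd_deletion	hgmd_insertion	kg_deletion	kg_insertion
1	1103	174	1007	311
2	185	75	103	71
3	164	64	59	28
4	105	28	58	9
5	73	31	25	3
6	79	32	17	5
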