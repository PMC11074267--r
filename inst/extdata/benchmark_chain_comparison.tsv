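emdb_id	resolution	pdb_id	residues	rmsd	matching_pct	seq_id_pct
22898	2.08	7KJR	448	1.09	80.4	86.7
30210	2.50	7BV2	1036	1.31	69.7	73.0
3061	3.4	5A63	1223	1.66	49.6	14.2
8117	2.95	5IRX	1726	1.64	50.0	28.2
6551	3.80	3JCF	1745	1.83	52.0	15.0
8764	2.94	5W3S	1940	1.56	58.5	30.7
25855	2.25	7TEY	2703	1.42	71.6	85.0
6634	3.30	3JD1	2976	1.71	52.3	13.2
2984	2.20	5A1A	4088	1.40	57.2	12.4
3295	2.3	5FTJ	4338	1.55	62.7	21.0
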