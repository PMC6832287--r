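# Bundled S1-domain registry: 9 bacterial, 10 eukaryotic, 5 archaeal entries.
# Columns: pdb_id chain start end kingdom protein_name group
# Residue ranges are curated defaults (Pfam S1-profile envelopes, author
# numbering) and are editable configuration: copy this file and adjust the
# ranges/chains to your needs. 'group' marks the same protein solved in
# different organisms; such pairs are excluded from identity extrema.
pdb_id	chain	start	end	kingdom	protein_name	group
1sro	A	1	76	bacteria	Polynucleotide_phosphorylase	pnpase
4aim	A	617	690	bacteria	Polynucleotide_phosphorylase	pnpase
1hh2	A	132	198	bacteria	Transcription_factor_NusA	nusa
5lm9	A	132	198	bacteria	Transcription_factor_NusA	nusa
5xgu	A	644	720	bacteria	Ribonuclease_R	.
5f6c	A	38	108	bacteria	Ribonuclease_E	.
2ix0	A	561	644	bacteria	RNase_II	.
3bzc	A	655	730	bacteria	Transcription_accessory_protein_Tex	.
2k4k	A	1	84	bacteria	General_stress_protein_13	.
1q46	A	17	87	eukaryota	eIF2_subunit_alpha	.
1wi5	A	9	78	eukaryota	Protein_RRP5_homolog	.
2eqs	A	10	79	eukaryota	RNA_helicase_DHX8	.
2cqo	A	8	78	eukaryota	Nucleolar_protein_of_40_kDa	.
2wp8	A	909	980	eukaryota	Exosome_exonuclease_DIS3	.
6gmh	G	35	105	eukaryota	RNA_polymerase_II_subunit_G	polg
6h25	A	909	980	eukaryota	Exosome_exonuclease_RRP44	.
6ir9	G	40	110	eukaryota	RNA_polymerase_II_subunit	polg
4a3g	G	62	135	eukaryota	RNA_polymerase_II_subunit_RPB7	.
2nn6	A	65	138	eukaryota	Exosome_component_RRP40	.
2ba0	A	66	130	archaea	Exosome_component_Rrp4	rrp4
2z0s	A	66	130	archaea	Exosome_component_Rrp4	rrp4
3l7z	A	60	125	archaea	Exosome_component_Csl4	.
1yz6	A	12	85	archaea	Translation_initiation_factor_2_alpha	aif2a
3aev	A	12	85	archaea	Translation_initiation_factor_2_alpha	aif2a
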