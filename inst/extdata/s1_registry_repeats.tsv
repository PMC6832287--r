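# Optional multi-repeat registry: N-terminal S1 repeats of 30S ribosomal
# protein S1 resolved in larger assemblies. One record per repeat; the
# protein_name suffix gives the repeat index. Ranges are curated defaults.
pdb_id	chain	start	end	kingdom	protein_name	group
4q7j	D	20	87	bacteria	Ribosomal_protein_S1_repeat_1	rpsA
4q7j	D	105	170	bacteria	Ribosomal_protein_S1_repeat_2	rpsA
6h4n	y	20	87	bacteria	Ribosomal_protein_S1_repeat_1	rpsA
6h4n	y	105	170	bacteria	Ribosomal_protein_S1_repeat_2	rpsA
6h4n	y	278	345	bacteria	Ribosomal_protein_S1_repeat_4	rpsA
6h4n	y	364	430	bacteria	Ribosomal_protein_S1_repeat_5	rpsA
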