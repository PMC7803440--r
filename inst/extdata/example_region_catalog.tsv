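chromosome	start	end	gene_symbol	drug_class	element_type
3	53528638	53847760	CACNA1D	CCB	gene_body
12	2162848	2807115	CACNA1C	CCB	gene_body
12	2110000	2162847	CACNA1C	CCB	promoter
10	114043866	114046904	ADRB1	BB	gene_body
5	148826593	148930983	ADRB2	BB	gene_body
17	63477061	63498380	ACE	ACEi	gene_body
3	148697871	148743003	AGTR1	ARB	gene_body
16	56899119	56949762	SLC12A3	thiazide	gene_body
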