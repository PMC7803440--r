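variant_id	gene	tissue	beta	se	p	drug_class
rs1051375	AGTR1	Artery_Tibial	0.58	0.06	2.1e-18	ARB
rs4149601	SCNN1G	Kidney_Cortex	0.31	0.08	9.0e-05	thiazide
rs7961030	CACNA1C	Heart_Left_Ventricle	0.42	0.05	3.4e-14	CCB
rs2429511	ADRB2	Lung	0.27	0.04	1.2e-10	BB
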