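# Proteins documented to bind thiamin compounds, or immediate interaction
# partners of such proteins, among the thiamin (T)- and DMHT (thiazolium)-
# eluted proteomes. Flags: + identified in that eluate, - not identified.
protein_id	protein_name	thiamin	thiazolium	partner
ODO1_RAT	2-oxoglutarate dehydrogenase, mitochondrial	-	+	ThDP
ODPA_RAT	Pyruvate dehydrogenase E1 subunit alpha, mitochondrial	-	+	ThDP
ODPB_RAT	Pyruvate dehydrogenase E1 subunit beta, mitochondrial	-	+	ThDP
TKT_RAT	Transketolase	+	+	ThDP
ALBU_RAT	Serum albumin	+	+	thiamin
ATPB_RAT	ATP synthase subunit beta, mitochondrial	-	+	ThDP, ThTP
HBA_RAT	Hemoglobin subunit alpha-1/2	+	+	thiamin
HBB1_RAT	Hemoglobin subunit beta-1	+	+	thiamin
HBB2_RAT	Hemoglobin subunit beta-2	+	+	thiamin
DHE3_RAT	Glutamate dehydrogenase 1, mitochondrial	-	+	OGDHC
DLDH_RAT	Dihydrolipoyl dehydrogenase, mitochondrial	-	+	OGDHC, PDHC
SUCA_RAT	Succinyl-CoA ligase (GDP-forming) subunit alpha, mitochondrial	+	-	OGDHC
CISY_RAT	Citrate synthase	-	+	PDHC
HSP72_RAT	Heat shock-related 70 kDa protein 2	-	+	OGDHC
HSP7C_RAT	Heat shock cognate 71 kDa protein	+	+	OGDHC
CH60_RAT	60 kDa heat shock protein, mitochondrial	-	+	OGDHC
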