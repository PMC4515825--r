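# Published physical and functional interactions among proteins of the
# thiamin (T) and thiazolium (Tz) eluates. Shipped as a reference fixture;
# no analysis in this package consumes it.
protein	partner	thiamin	thiazolium	interaction_type
Malate dehydrogenase (mitochondrial)	Glutamate dehydrogenase	-	+	protein-protein
Malate dehydrogenase (mitochondrial)	Citrate synthase	-	+	protein-protein
Malate dehydrogenase (mitochondrial)	Aspartate aminotransferase (mitochondrial)	+	+	protein-protein
Glutamate dehydrogenase	Malate dehydrogenase (mitochondrial)	-	+	protein-protein
Glutamate dehydrogenase	Aspartate aminotransferase (mitochondrial)	-	+	protein-protein
Pyridoxal kinase	Aspartate aminotransferase	+	+	protein-protein
14-3-3	Pyridoxal kinase	+	+	protein-protein
14-3-3	Profilin	-	+	protein-protein
14-3-3	Actin	+	+	protein-protein
14-3-3	Tubulin	-	+	protein-protein
14-3-3	PP1-alpha	-	+	protein-protein
14-3-3	Casein kinase II	+	-	protein-protein
14-3-3	Peroxiredoxin 2	-	+	protein-protein
14-3-3	Peroxiredoxin 5	-	+	protein-protein
14-3-3	Peroxiredoxin 6	-	+	protein-protein
14-3-3	HSP70	+	+	protein-protein
14-3-3	Glutamine synthase	+	-	protein-protein; functional (concomitant oxidation in amyloid-beta neurotoxicity)
Calmodulin	V-type ATPase, subunit A	-	+	protein-protein
Calmodulin	BASP1	-	+	protein-protein
Calmodulin	MARCKS	-	+	protein-protein
Calmodulin	Synapsin	-	+	protein-protein
V-type ATPase (subunits A, B, D, E1)	Aldolase A, C	+	-	protein-protein
BASP1	MARCKS	-	+	protein-protein
BASP1	Actin	-	+	protein-protein
MARCKS	HSP70	-	+	protein-protein
MARCKS	Actin	-	+	protein-protein
Synapsin	Rab3A	-	+	functional (Rab3A inhibits synapsin I binding to F-actin)
Synapsin	Spectrin	-	+	protein-protein
Synapsin	F-actin	-	+	protein-protein, phosphorylation-dependent
Peroxiredoxin 6	Glutathione-S-transferase Pi	-	+	functional (catalytic-cysteine oxidation required)
Peroxiredoxin 6	Amyloid beta A4 protein	-	+	functional (protects against amyloid-beta neurotoxicity)
Amyloid beta A4 protein	Serum albumin	-	+	protein-protein
Amyloid beta A4 protein	Protein phosphatase 2A	-	+	protein-protein
Glutamate receptor 2 (GRIA2)	Tubulin	-	+	protein-protein
Glutamate receptor 2 (GRIA2)	WW domain-binding protein 2	+	-	functional (WWP2 regulates ADAR2 levels)
Glutamate receptor 2 (GRIA2)	Casein kinase II	+	-	functional (phosphorylates GRIA2)
Ubiquitin-dependent proteins	Ubiquitin carboxyl-terminal hydrolase 1	-	+	ubiquitin system
Endophilin	Synaptojanin	-	+	protein-protein
Endophilin	PP1-alpha	-	+	protein-protein
Aldose reductase	Hydroxyacylglutathione hydrolase (glyoxalase II)	+	-	methylglyoxal metabolism
Aldose reductase	Tubulin	-	+	protein-protein
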