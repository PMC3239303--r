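# Database event templates: ID<TAB>TEMPLATE<TAB>LABEL
T1	<RegulationOfGeneExpression hasAgent=?Protein hasPatient=<GeneExpression hasPatient=?Gene>>	Regulation of gene expression(GO:0010468)
T2	<RegulationOfTranscription hasAgent=?Protein hasPatient=<Transcription hasPatient=?Gene>>	Regulation of transcription(GO:0045449)
T3	<BindingOfTFToTFBindingSiteOfDNA hasAgent=?TranscriptionFactor hasPatient=<RegulatoryDNARegion hasPatient=?Gene>>	Transcription factor binding(GO:0008134)
T4	<RegulatoryProcess hasAgent=?MolecularEntity hasPatient=<CellGrowth hasAgent=?Cell>>	Regulation of cell growth(GO:0001558)
T5	<RegulatoryProcess hasAgent=?MolecularEntity hasPatient=<CellDeath hasAgent=?Cell>>	Regulation of cell killing(GO:0031341)
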