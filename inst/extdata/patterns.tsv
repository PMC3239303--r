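# Syntactic-semantic paired patterns: ID<TAB>SYNTACTIC<TAB>SEMANTIC.
# Core gene-regulation vocabulary (expression/reduction/lesion/cause),
# followed by support vocabulary for activation, repression, regulation and
# binding-site sentences used by the synthetic corpus generator.
P01	(expression_Noun (of_Prep Object:Gene))	<GeneExpression hasPatient=Gene>
P02	(reduction_Noun (in_Prep Object:Patient))	<RegulatoryProcess hasPatient=Patient hasPolarity="negative">
P03	(lesion_Noun Object:Patient)	<RegulatoryProcess hasPatient=Patient hasPolarity="negative">
P04	(cause_Verb Subject:Agent Object:Patient)	<RegulatoryProcess hasAgent=Agent hasPatient=Patient>
P05	(activate_Verb Subject:Agent Object:GeneExpression)	<RegulationOfGeneExpression hasAgent=Agent hasPatient=GeneExpression hasPolarity="positive">
P06	(repress_Verb Subject:Agent Object:GeneExpression)	<RegulationOfGeneExpression hasAgent=Agent hasPatient=GeneExpression hasPolarity="negative">
P07	(regulate_Verb Subject:Agent Object:Patient)	<RegulatoryProcess hasAgent=Agent hasPatient=Patient>
P08	(contain_Verb Subject:Gene Object:TFBS)	<RegulatoryDNARegion hasAgent=Gene hasPart=TFBS>
P09	(site_Noun TranscriptionFactor)	<TFBS hasAgent=TranscriptionFactor>
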