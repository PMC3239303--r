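# Miniature Gene Regulation Ontology: concepts and properties used by the
# shipped patterns, inference rules and extraction templates.
# Entities
concept MolecularEntity
concept Gene
concept Protein
concept TranscriptionFactor
concept Operon
concept RegulatoryDNARegion
concept TranscriptionFactorBindingSiteOfDNA
concept Cell
# Processes
concept Process
concept GeneExpression
concept Transcription
concept CellGrowth
concept CellDeath
concept RegulatoryProcess
concept RegulationOfGeneExpression
concept RegulationOfTranscription
concept PositiveRegulation
concept NegativeRegulation
concept BindingOfTFToTFBindingSiteOfDNA

isa Gene MolecularEntity
isa Protein MolecularEntity
isa Operon MolecularEntity
isa TranscriptionFactor Protein
isa RegulatoryDNARegion MolecularEntity
isa TranscriptionFactorBindingSiteOfDNA RegulatoryDNARegion
isa GeneExpression Process
isa Transcription GeneExpression
isa CellGrowth Process
isa CellDeath Process
isa RegulatoryProcess Process
isa RegulationOfGeneExpression RegulatoryProcess
isa RegulationOfTranscription RegulationOfGeneExpression
isa PositiveRegulation RegulatoryProcess
isa NegativeRegulation RegulatoryProcess
isa BindingOfTFToTFBindingSiteOfDNA RegulatoryProcess

property hasAgent
property hasPatient
property hasPolarity
property hasPhysicalContact
property hasPart

alias TFBS TranscriptionFactorBindingSiteOfDNA
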