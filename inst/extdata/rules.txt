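# Inference rules: RULEID: <Cond1> + <Cond2> => <Conclusion>
# R1/R2 flatten cascaded regulation structures (polarities compose as NXOR);
# R3 specializes regulation of a gene-expression patient; R4 combines a
# regulation event with cross-sentence binding-site evidence into a direct
# (physical-contact) transcription regulation event.
R1: <RegulatoryProcess hasPolarity=Polarity2 hasAgent=<RegulatoryProcess hasPatient=Patient hasPolarity=Polarity1>> => <RegulatoryProcess hasAgent=Patient hasPolarity=polarity_sum(Polarity1,Polarity2)>
R2: <RegulatoryProcess hasPolarity=Polarity2 hasPatient=<RegulatoryProcess hasPatient=Patient hasPolarity=Polarity1>> => <RegulatoryProcess hasPatient=Patient hasPolarity=polarity_sum(Polarity1,Polarity2)>
R3: <RegulatoryProcess hasPatient=GeneExpression> => <RegulationOfGeneExpression hasPatient=GeneExpression>
R4: <RegulationOfGeneExpression hasAgent=TranscriptionFactor hasPatient=<GeneExpression hasPatient=Gene>> + <RegulatoryDNARegion hasAgent=Gene hasPart=<TFBS hasAgent=TranscriptionFactor>> => <RegulationOfTranscription hasAgent=TranscriptionFactor hasPatient=<Transcription hasPatient=Gene> hasPhysicalContact="yes">
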