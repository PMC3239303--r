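# regevents

Ontology-based extraction of gene-regulation events from dependency-parsed
biomedical text.

## The problem

Curated regulatory databases record edges such as *transcription factor X
regulates the expression of gene Y*, but the literature rarely states such
facts in a single database-shaped sentence. Instead it writes compositional
descriptions — "lesions in *himA* cause a reduction in expression of *fimA*"
— where one event (a reduction of expression) is itself the participant of
another (the lesions causing it), and it spreads evidence across sentences
("X regulates the expression of Y." … "The regulatory region of Y contains an
X binding site."). `regevents` is for text-mining and systems-biology users
who want to turn pre-parsed abstracts into grounded regulatory-network edges,
and for method developers who want a compact, fully testable implementation
of ontology-based event composition and inference.

The pipeline has four stages, all grounded in a miniature Gene Regulation
Ontology (an is-a DAG of concepts such as
`TranscriptionFactor ⊑ Protein ⊑ MolecularEntity` and
`RegulationOfTranscription ⊑ RegulationOfGeneExpression ⊑ RegulatoryProcess`,
plus the properties `hasAgent`, `hasPatient`, `hasPolarity`,
`hasPhysicalContact`, `hasPart`):

1. **Named-entity recognition** — dictionary lookup (longest match,
   non-overlapping) yielding grounded mentions with concept labels.
2. **Pattern matching** — syntactic–semantic paired patterns such as

   ```
   (cause_Verb Subject:Agent Object:Patient)   <RegulatoryProcess hasAgent=Agent hasPatient=Patient>
   ```

   are matched bottom-up over each dependency tree; a matched pattern's
   semantic structure is instantiated with the semantics of the matched
   descendants, composing phrase semantics into sentence semantics (an
   *explicit event*). Matching is *loose*: a dependent item may match any
   descendant of the head node, subject to (1) role-subtree confinement,
   (2) no re-use of a matched node's subtree by another item, and (3) no
   crossing of clausal boundaries (`which`, `that`, …) or exception words
   (`except`, `unless`, `without`).
3. **Inference** — forward chaining with modus ponens over `P → Q` rules
   until fixpoint, per document. Flattening rules rewrite nested regulation
   cascades into database-shaped events, composing nested polarities as NXOR
   (`polarity_sum(negative, negative) = positive`; `positive` is the
   identity, `unknown` absorbs); an evidence-combination rule merges a
   regulation event with a cross-sentence binding-site event into a
   physical-contact transcription-regulation event (*implicit events*).
4. **Extraction** — events (explicit or implicit) matching database
   templates such as
   `<RegulationOfGeneExpression hasAgent=?Protein hasPatient=<GeneExpression hasPatient=?Gene>>`
   become grounded records; subsumption makes a more specific event satisfy
   a more general template. An evaluation module scores records on agent,
   patient and event type, and a seeded synthetic-corpus generator provides
   gold-annotated fixtures for the full pipeline and the with/without
   inference ablation.

## Worked example

```r
library(regevents)
ont       <- load_ontology()
patterns  <- load_patterns(ont = ont)
rules     <- load_rules(ont = ont)
templates <- load_templates(ont = ont)

dict_file <- tempfile(fileext = ".tsv")
write.table(rbind(make_dict_rows(tfs = c("himA", "himD")),
                  make_dict_rows(genes = "fimA")),
            dict_file, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
dict <- load_dictionary(dict_file, ont)

## "lesions in himA cause a reduction in expression of fimA"
graph    <- read_conllu(frame_sentence("cascade", agent = "himA", patient = "fimA"))[[1]]
mentions <- recognize(graph, dict)
events   <- compose(graph, mentions, patterns, ont)
print(events[[1]])
#> <gr_event explicit P04 doc=doc1 sent=1>
#>   <RegulatoryProcess hasAgent=<RegulatoryProcess hasPatient=@ID_himA hasPolarity="negative">
#>    hasPatient=<RegulatoryProcess hasPatient=<GeneExpression hasPatient=@ID_fimA> hasPolarity="negative">>
```

The explicit event is a cascade of four basic event instances (three
`RegulatoryProcess`, one `GeneExpression`): lesions in *himA* (a negative
regulation of *himA*) cause a reduction (a negative regulation) of the
expression of *fimA*. The closure flattens it — the two negatives cancel:

```r
all_events <- closure(events, rules, ont)
flat <- Filter(function(e) e$struct$concept == "RegulationOfGeneExpression" &&
                           is_sem_entity(e$struct$slots$hasAgent), all_events)
print(flat[[1]])
#> <gr_event inferred R3 doc=doc1 sent=1>
#>   <RegulationOfGeneExpression hasAgent=@ID_himA hasPatient=<GeneExpression hasPatient=@ID_fimA> hasPolarity="positive">

records <- extract_records(all_events, templates, ont)
records[, c("template", "agent_surface", "patient_surface", "polarity", "origin")]
#>   template agent_surface patient_surface polarity   origin
#> 1       T1          himA            fimA positive inferred
```

So *himA* positively regulates the expression of *fimA* — a record no
single pattern could produce, derivable only through inference.

A shell interface wraps the same functions:

```sh
exec/regevents generate --out corpus --seed 5 --n-docs 20
exec/regevents extract --conllu corpus/doc001.conllu --dict corpus/dictionary.tsv --out out
exec/regevents extract --no-inference ...   # ablation
```

writing nested-event JSON, BioNLP-style standoff (`.a1`/`.a2`) and an edge
TSV (doc, agent, patient, type, polarity, physical contact).

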