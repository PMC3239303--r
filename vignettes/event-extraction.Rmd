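---
title: "Composing and inferring gene-regulation events from dependency trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing and inferring gene-regulation events from dependency trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regevents)
```

## The model

`regevents` represents everything — pattern semantics, rule conditions and
conclusions, database templates, and events themselves — as one recursive
data type, the *semantic structure*: a concept-rooted attribute structure
`<Concept prop=value ...>` whose values are nested structures, grounded
entity references, string literals, or (in patterns, rules and templates)
variables. Concepts and properties come from a miniature Gene Regulation
Ontology shipped as a plain-text is-a DAG. The uniformity is the point: the
same one-way unification procedure (ground value against pattern, with
subsumption on concepts and "extra slots permitted") drives rule matching
and template matching, and a single canonical serialization (slots sorted,
entities by grounding id) defines event identity everywhere.

An *explicit event* is a variable-free structure composed from one sentence
by pattern matching. An *implicit event* is deduced from explicit events by
forward chaining. A *complex* event is one whose participant is itself an
event; `basic_instances()` counts its concept-rooted nodes.

### Bottom-up composition with loose matching

Patterns pair a syntactic side with a semantic side, e.g.

```
(reduction_Noun (in_Prep Object:Patient))    <RegulatoryProcess hasPatient=Patient hasPolarity="negative">
```

Composition walks each dependency tree in post-order. Entity mentions seed
atomic semantics at their head tokens; at each node every pattern is tried,
and a match instantiates the semantic side with the semantics of the matched
descendants, stacking the result onto the node (a node may carry several
structures — all matches accumulate, which is also how coordination yields
one reading per conjunct). A structure later consumed as a variable filler
is not emitted on its own; the maximal structures become the sentence's
explicit events. Because patterns are phrase-level, the head of a matched
dependent need not be a direct child: matching is *loose*, with three
restrictive conditions.

1. *Role confinement.* An item with a syntactic role matches a descendant
   only if the downward path from the head (head-exclusive,
   candidate-inclusive) passes through a node bearing that role. We chose
   the on-path reading — rather than "descendant of a role-bearing direct
   child" — because prepositional objects sit below function words: in
   "lesions in himA", *himA* is only reachable for `Object:Patient` through
   the prepositional object on the path. For the same reason the pattern
   role `Object` accepts both direct and prepositional objects.
2. *No re-use.* Two items of one pattern instance may not match nodes in
   each other's subtrees (items in a pattern ancestor–descendant relation
   are exempt, since a nested item necessarily matches inside its parent's
   subtree).
3. *No clause crossing.* The path may not cross a clausal boundary or
   exception word. A boundary is crossed when an intermediate path node is,
   or directly governs (as with a relativizer attached to its clause head),
   a word from the configurable lists: boundaries
   `which, that, who, whose, when, where, because, although`; exceptions
   `except, unless, without` (`match_control()`).

When several descendants satisfy one item, candidates are ranked by tree
depth, then surface position; alternatives are kept only when they bind a
distinct set of mentions. This collapses vacuous ambiguity (binding the
phrase head's structure vs. the entity inside it — same mention, same
record) while preserving genuine ambiguity such as coordination, where each
conjunct contributes a distinct mention set. Head matching is lemma-based,
so `cause` matches `caused`; entity matching is token-level, contiguous and
case-sensitive by default (`fimA` vs `FimA` differ; `recognize(...,
case_sensitive = FALSE)` relaxes this), longest-match and non-overlapping.

### Forward chaining

Rules have the form `P → Q`; with matched conditions `P` the instantiated
conclusion `Q` is added (modus ponens), and all rules are re-applied until a
pass adds nothing new under canonical-form deduplication. Closure scope is
the document, which is what lets a rule combine evidence from different
sentences. Two conventions matter and are deliberate:

* **Missing polarity defaults to positive.** A condition slot
  `hasPolarity=Var` matches an event lacking polarity by binding
  `"positive"`. Since `positive` is the NXOR identity of `polarity_sum`,
  polarity-less events compose inertly — a causal verb with no stated
  direction neither flips nor fixes the sign of what it embeds.
* **Slot carry-over.** Top-level slots of the first condition's matched
  event that the condition does not mention and the conclusion does not set
  are copied into the conclusion. The shipped flattening rules mention only
  the slots they rearrange; without carry-over, flattening a cascade would
  drop the participant on the other side (the conclusion of the
  agent-flattening rule names no patient), and no chain of the shipped
  rules could produce a two-participant database event. With it, the
  cascade "lesions in himA cause a reduction in expression of fimA"
  flattens to `RegulationOfGeneExpression(agent=himA,
  patient=GeneExpression(fimA), polarity=positive)` — two negatives
  cancelling — independent of rule application order.

Termination is guaranteed for the shipped rules (no conclusion nests deeper
than its conditions); a configurable iteration cap (default 100 passes)
guards user-supplied rule sets, and exceeding it is an error, not a silent
truncation. Closure never removes or mutates input events; every inferred
event's provenance chain bottoms out in explicit events.

### Extraction and scoring

Templates restrict events by fixed structure and bind `?Concept` variables
to grounded entities (label subsumption; an entity may carry several labels
— a gene name used for its product satisfies `?Protein`, which is how
metonymy is handled). Records are deduplicated on (document, template,
bindings, polarity, contact). `evaluate_records()` scores agent, patient and
event type; the type check is directional by subsumption (a predicted
`RegulationOfTranscription` satisfies a gold `RegulationOfGeneExpression`),
and polarity/contact are reported but not scored — they are properties of a
correctly extracted event, not part of its identity. `mode = "unique"`
collapses per-document duplicates, the protocol for counting unique
database events.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| boundary / exception word lists | see above | clause edges and counterfactual contexts are where loose matching over-reaches |
| `case_sensitive` (NER) | `TRUE` | short gene symbols are case-meaningful |
| missing-polarity default | `"positive"` | NXOR identity; inert under composition |
| closure `max_passes` | 100 | safety cap for user rules; shipped rules converge in ≤ 4 passes |
| fixture frame weights | direct 2, cascade 2, coordination 1, binding 2, distractor 1 | every construction exercised; about two-thirds of gold records require inference |
| fixture inventories | 15 TFs, 40 genes | small enough to read, large enough that seeded draws rarely collide |

## What the synthetic generator does and does not show

`generate_fixtures()` emits five sentence frames from fixed hand-written
tree skeletons (Stanford-dependency style, prepositions heading their
objects) with names substituted: direct regulation
("X activates/represses the expression of Y", extractable without
inference), the nominalized cascade, its coordination variant
("X or X2"), a cross-sentence binding pair
("X regulates the expression of Y." + "The regulatory region of Y contains
an X binding site."), and pattern-free distractors. Gold explicit events
and gold records (flagged `requires_inference`) are derived by hand per
frame, so pipeline completeness — 100% recall, zero false positives with
inference; exactly the explicit subset without — is an exact check of the
implementation against the frames' intended derivations, and the ablation
direction (recall drops sharply without inference, precision does not)
falls out of the frame mix.

What passing these tests does *not* show: robustness to real parser output
(skeletons have no attachment errors), lexical variety (nine patterns, four
rules), negation (cues are flagged in provenance but never interpreted),
anaphora (out of scope), or real-corpus precision/recall levels. The
generator is a correctness harness, not a corpus simulator.

## Numerical and degenerate-input choices

Ties among match candidates break by (depth, surface position, insertion
order). Empty inputs are well-defined everywhere: an empty dictionary
recognizes nothing, a sentence without matches composes no events, closure
of an empty event set is empty, extraction of no events yields a zero-row
record table, and precision/recall are 0 when undefined. Ontology loading
rejects cycles, undeclared edge endpoints and dangling aliases at load
time; CoNLL-U reading rejects cyclic heads, multiple roots and
non-contiguous indices with sentence numbers in the error.

Problem sizes in the shipped tests and acceptance script were chosen for
exactness of their oracles: random-DAG subsumption checks up to 30
concepts; exhaustive match enumeration on trees of up to 8 nodes; closure
law checks on 50 randomized small event sets against an independent
re-scan oracle; the ablation corpus is 30–40 documents.

## Known limitations

* The shipped pattern and rule inventories cover the constructions of the
  fixture frames plus the core regulation vocabulary; real corpora need
  larger inventories (both files are plain-text DSLs meant to be extended).
* One-way unification only: conditions match ground events; there is no
  event–event unification and no backward chaining.
* The on-path reading of role confinement is a declared choice; corpora
  with different conventions can remap roles via the tag map
  (`default_tagmap()` accepts an override file).
* Inferred events re-use the trigger of supporting explicit events in
  standoff output, since deduction has no text anchor of its own.
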