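test_that("rule parsing handles nesting, shared variables, calls and errors", {
  ont <- test_ontology()
  r1 <- parse_rule(paste0(
    "R1: <RegulatoryProcess hasPolarity=Polarity2 hasAgent=",
    "<RegulatoryProcess hasPatient=Patient hasPolarity=Polarity1>> => ",
    "<RegulatoryProcess hasAgent=Patient hasPolarity=polarity_sum(Polarity1,Polarity2)>"),
    ont)
  expect_identical(r1$id, "R1")
  expect_length(r1$conditions, 1L)
  expect_true(is_sem_struct(r1$conditions[[1]]$slots$hasAgent))
  concl_pol <- r1$conclusion$slots$hasPolarity
  expect_identical(concl_pol$fn, "polarity_sum")
  expect_identical(concl_pol$args, c("Polarity1", "Polarity2"))

  r4 <- test_rules()[[4]]
  expect_length(r4$conditions, 2L)
  shared <- intersect(sem_vars(r4$conditions[[1]]), sem_vars(r4$conditions[[2]]))
  expect_setequal(shared, c("TranscriptionFactor", "Gene"))

  expect_error(parse_rule(
    "RX: <RegulatoryProcess hasAgent=A> => <RegulatoryProcess hasAgent=B>", ont),
    "not bound")
  expect_error(parse_rule("RX: <Gene> <Gene>", ont), "'=>'")
})

test_that("polarity_sum is NXOR with identity positive and absorbing unknown", {
  expect_identical(polarity_sum("positive", "positive"), "positive")
  expect_identical(polarity_sum("negative", "negative"), "positive")
  expect_identical(polarity_sum("positive", "negative"), "negative")
  expect_identical(polarity_sum("negative", "positive"), "negative")
  expect_identical(polarity_sum("unknown", "negative"), "unknown")
  expect_identical(polarity_sum("positive", "unknown"), "unknown")
  expect_error(polarity_sum("up", "down"), "polarity")
})

test_that("condition matching uses subsumption, requires slots, defaults polarity", {
  ont <- test_ontology()
  r3cond <- test_rules()[[3]]$conditions[[1]]
  ev <- gr_event(sem_struct("RegulatoryProcess", list(
    hasAgent = sem_entity("U1", "araC", c("Gene", "Protein", "TranscriptionFactor")),
    hasPatient = sem_struct("GeneExpression",
                            list(hasPatient = sem_entity("U2", "araB", "Gene"))))),
    origin = "explicit", doc = "d", sentences = 1L, source = "P07")
  b <- match_condition(r3cond, ev, list(), ont)
  expect_length(b, 1L)
  expect_identical(b[[1]]$GeneExpression$concept, "GeneExpression")

  ## subsumption: a NegativeRegulation event satisfies a RegulatoryProcess condition
  ev2 <- gr_event(sem_struct("NegativeRegulation", list(
    hasPatient = sem_struct("GeneExpression",
                            list(hasPatient = sem_entity("U2", "araB", "Gene"))))),
    origin = "explicit", doc = "d", sentences = 1L, source = "P06")
  expect_length(match_condition(r3cond, ev2, list(), ont), 1L)

  ## a condition demanding hasAgent fails on an event lacking it
  cond <- parse_sem("<RegulatoryProcess hasAgent=Agent>", ont)
  expect_length(match_condition(cond, ev2, list(), ont), 0L)

  ## missing polarity binds the default positive (NXOR identity)
  cond_pol <- parse_sem("<RegulatoryProcess hasPolarity=Pol>", ont)
  b2 <- match_condition(cond_pol, ev2, list(), ont)
  expect_identical(b2[[1]]$Pol, "positive")

  ## inconsistent rebinding is rejected
  prior <- list(Pol = "negative")
  expect_length(match_condition(cond_pol, ev2, prior, ont), 0L)
})

test_that("closure flattens the cascade into the derived implicit event", {
  ont <- test_ontology()
  ex <- cascade_example()
  out <- closure(ex$events, test_rules(), ont)
  canon <- event_canon(out)
  expect_true(paste0("<RegulationOfGeneExpression hasAgent=@ID_himA ",
                     "hasPatient=<GeneExpression hasPatient=@ID_fimA> ",
                     "hasPolarity=\"positive\">") %in% canon)
  ## provenance chains bottom out in explicit events
  leaves <- function(e) {
    if (e$origin == "explicit") return(TRUE)
    length(e$supports) > 0 && all(vapply(e$supports, leaves, TRUE))
  }
  expect_true(all(vapply(out, leaves, TRUE)))
})

test_that("the binding-site rule combines evidence across sentences", {
  ont <- test_ontology()
  gs <- read_conllu(frame_sentence("binding", agent = "himA", patient = "fimA"))
  evs <- list()
  for (g in gs) {
    ms <- recognize(g, him_dictionary())
    evs <- c(evs, compose(g, ms, test_patterns(), ont))
  }
  out <- closure(evs, test_rules(), ont)
  rot <- Filter(function(e) e$struct$concept == "RegulationOfTranscription", out)
  expect_length(rot, 1L)
  expect_identical(rot[[1]]$struct$slots$hasPhysicalContact, "yes")
  expect_identical(rot[[1]]$origin, "inferred")
  expect_identical(rot[[1]]$source, "R4")
  expect_identical(rot[[1]]$sentences, c(1L, 2L))
  expect_identical(canonical_form(rot[[1]]$struct$slots$hasPatient),
                   "<Transcription hasPatient=@ID_fimA>")
})

test_that("closure with an empty rule set is the identity", {
  ex <- cascade_example()
  expect_identical(event_canon(closure(ex$events, list(), test_ontology())),
                   event_canon(ex$events))
})

test_that("closure is extensive, idempotent, monotone and matches a naive oracle", {
  ont <- test_ontology()
  rules <- test_rules()[1:3]
  set.seed(5)
  for (rep in 1:15) {
    structs <- replicate(sample(1:3, 1L), random_event_struct(), simplify = FALSE)
    evs <- as_events(structs)
    out <- closure(evs, rules, ont)
    ## extensive
    expect_true(all(event_canon(evs) %in% event_canon(out)))
    ## idempotent
    expect_identical(event_canon(closure(out, rules, ont)), event_canon(out))
    ## equals independent re-scan oracle
    expect_setequal(event_canon(out),
                    vapply(oracle_closure(structs), canonical_form, ""))
    ## monotone: adding an event never loses conclusions
    extra <- as_events(list(random_event_struct()))
    bigger <- closure(c(evs, extra), rules, ont)
    expect_true(all(event_canon(out) %in% event_canon(bigger)))
  }
})

test_that("a self-feeding rule set hits the iteration cap", {
  ont <- test_ontology()
  ## grows a fresh nesting level each pass: no fixpoint
  runaway <- parse_rule(paste0(
    "RX: <RegulatoryProcess hasPatient=Patient> => ",
    "<RegulatoryProcess hasPatient=<RegulatoryProcess hasPatient=Patient>>"), ont)
  ev <- as_events(list(sem_struct("RegulatoryProcess",
                                  list(hasPatient = sem_entity("U1", "x", "Gene")))))
  expect_error(closure(ev, list(runaway), ont, max_passes = 10L), "fixpoint")
})
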