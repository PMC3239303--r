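test_that("templates match by subsumption and bind entities to ?Concept variables", {
  ont <- test_ontology()
  tpls <- test_templates()
  flat <- gr_event(sem_struct("RegulationOfGeneExpression", list(
    hasAgent = sem_entity("ID_himA", "himA", c("Gene", "Protein", "TranscriptionFactor")),
    hasPatient = sem_struct("GeneExpression",
                            list(hasPatient = sem_entity("ID_fimA", "fimA", "Gene"))),
    hasPolarity = "positive")),
    origin = "inferred", doc = "d1", sentences = 1L, source = "R3")
  rec <- match_template(tpls[[1]], flat, ont)
  expect_identical(rec$agent_id, "ID_himA")
  expect_identical(rec$patient_id, "ID_fimA")
  expect_identical(rec$polarity, "positive")

  ## cell-activity template: NegativeRegulation is a child of RegulatoryProcess
  cell <- gr_event(sem_struct("NegativeRegulation", list(
    hasAgent = sem_entity("ID_gX", "geneX", "Gene"),
    hasPatient = sem_struct("CellDeath",
                            list(hasAgent = sem_entity("ID_cY", "cellY", "Cell"))))),
    origin = "explicit", doc = "d1", sentences = 1L, source = "Pxx")
  rec5 <- match_template(tpls[[5]], cell, ont)
  expect_identical(rec5$template, "T5")
  expect_identical(rec5$agent_id, "ID_gX")
  expect_identical(rec5$patient_id, "ID_cY")
  ## but not the growth template (CellDeath is not CellGrowth)
  expect_null(match_template(tpls[[4]], cell, ont))

  ## an event without the embedded structure does not match
  bare <- gr_event(sem_struct("RegulationOfGeneExpression", list(
    hasAgent = sem_entity("ID_himA", "himA", "Protein"),
    hasPatient = sem_entity("ID_fimA", "fimA", "Gene"))),
    origin = "explicit", doc = "d1", sentences = 1L, source = "Pxx")
  expect_null(match_template(tpls[[1]], bare, ont))

  ## agent lacking a Protein label fails the variable constraint
  gene_agent <- flat
  gene_agent$struct$slots$hasAgent <- sem_entity("ID_g1", "g1", "Gene")
  expect_null(match_template(tpls[[1]], gene_agent, ont))
})

test_that("extraction pools explicit and inferred events and deduplicates", {
  ont <- test_ontology()
  ex <- cascade_example()
  all_ev <- closure(ex$events, test_rules(), ont)
  recs <- extract_records(all_ev, test_templates(), ont)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$template, "T1")
  expect_identical(recs$origin, "inferred")
  ## duplicated events collapse to a single record
  recs2 <- extract_records(c(all_ev, all_ev), test_templates(), ont)
  expect_identical(nrow(recs2), 1L)
  ## empty input
  expect_identical(nrow(extract_records(list(), test_templates(), ont)), 0L)
  ## soundness: the record's supporting event re-verifies under its template
  tpl <- Filter(function(t) t$id == recs$template, test_templates())[[1]]
  expect_false(is.null(match_template(tpl, all_ev[[recs$event]], ont)))
})

test_that("evaluation scores participants and roles, with subsumption on types", {
  ont <- test_ontology()
  recs <- data.frame(doc = c("d1", "d1"), type = "RegulationOfGeneExpression",
                     agent_id = c("A", "B"), patient_id = c("P", "Q"),
                     stringsAsFactors = FALSE)
  m <- evaluate_records(recs, recs, ont)
  expect_identical(c(m$precision, m$recall, m$f), c(1, 1, 1))

  none <- recs[0, ]
  m0 <- evaluate_records(none, recs, ont)
  expect_identical(m0$recall, 0)
  expect_identical(m0$fn, 2L)

  ## a more specific predicted type satisfies a more general gold type
  spec <- recs
  spec$type <- "RegulationOfTranscription"
  expect_identical(evaluate_records(spec, recs, ont)$precision, 1)
  ## but not the other way around
  gen <- recs
  gen$type <- "RegulatoryProcess"
  expect_identical(evaluate_records(gen, recs, ont)$tp, 0L)

  ## swapping predicted and gold swaps precision and recall (equal types)
  a <- recs
  b <- rbind(recs, data.frame(doc = "d1", type = "RegulationOfGeneExpression",
                              agent_id = "C", patient_id = "R"))
  mab <- evaluate_records(a, b, ont)
  mba <- evaluate_records(b, a, ont)
  expect_identical(mab$precision, mba$recall)
  expect_identical(mab$recall, mba$precision)

  ## unique mode collapses per-document duplicates
  dup <- rbind(recs, recs)
  expect_identical(evaluate_records(dup, recs, ont, mode = "unique")$tp, 2L)
  expect_identical(evaluate_records(dup, recs, ont, mode = "instance")$tp, 4L)
})

test_that("precision arithmetic: 79 TP and 15 FP give 84.0%", {
  m <- metrics(tp = 79L, fp = 15L, fn = 296L)
  expect_equal(round(100 * m$precision, 1), 84.0)
})

test_that("JSON event output round-trips", {
  ont <- test_ontology()
  ex <- cascade_example()
  evs <- closure(ex$events, test_rules(), ont)
  path <- tempfile(fileext = ".json")
  write_events_json(evs, path)
  back <- read_events_json(path)
  expect_identical(event_canon(back), event_canon(evs))
  expect_identical(vapply(back, `[[`, "", "origin"), vapply(evs, `[[`, "", "origin"))
  expect_identical(vapply(back, `[[`, "", "source"), vapply(evs, `[[`, "", "source"))
  ## support references survive by index
  inferred <- Filter(function(e) e$origin == "inferred", back)
  expect_true(all(vapply(inferred, function(e) length(e$supports) > 0, TRUE)))
})

test_that("standoff output parses under a strict grammar with resolved ids", {
  ont <- test_ontology()
  g <- read_conllu(frame_sentence("cascade"), default_tagmap())
  ms <- recognize(g[[1]], him_dictionary(), doc = "docA")
  evs <- compose(g[[1]], ms, test_patterns(), ont, doc = "docA")
  evs <- closure(evs, test_rules(), ont)
  dir <- tempfile()
  write_standoff(evs, ms, dir, graphs = list(docA = g))
  a1 <- readLines(file.path(dir, "docA.a1"))
  a2 <- readLines(file.path(dir, "docA.a2"))
  expect_true(all(grepl("^T[0-9]+\t[A-Za-z]+ [0-9]+ [0-9]+\t.+$", a1)))
  tlines <- grep("^T", a2, value = TRUE)
  elines <- grep("^E", a2, value = TRUE)
  alines <- grep("^A", a2, value = TRUE)
  expect_true(all(grepl("^T[0-9]+\t[A-Za-z]+ [0-9]+ [0-9]+\t.*$", tlines)))
  expect_true(all(grepl("^E[0-9]+\t[A-Za-z]+:T[0-9]+( [A-Za-z]+:[TE][0-9]+)*$", elines)))
  expect_true(all(grepl("^A[0-9]+\t[A-Za-z]+ E[0-9]+ [A-Za-z]+$", alines)))
  defined <- c(sub("\t.*", "", a1), sub("\t.*", "", a2))
  refs <- unlist(regmatches(a2, gregexpr("[TE][0-9]+", a2)))
  expect_true(all(refs %in% defined))
  expect_true(length(elines) > 0)

  ## empty record/event lists still give valid (empty) files
  dir2 <- tempfile()
  write_outputs(empty_rec <- extract_records(list(), test_templates(), ont),
                list(), list(), dir2)
  expect_true(file.exists(file.path(dir2, "edges.tsv")))
  expect_identical(length(readLines(file.path(dir2, "edges.tsv"))), 1L)  # header
  expect_identical(jsonlite::read_json(file.path(dir2, "events.json")), list())
})

test_that("edge tables carry the regulatory-network columns", {
  ont <- test_ontology()
  ex <- cascade_example()
  recs <- extract_records(closure(ex$events, test_rules(), ont),
                          test_templates(), ont)
  path <- tempfile(fileext = ".tsv")
  write_edges(recs, path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_identical(names(tab), c("doc", "agent_id", "patient_id", "type",
                                 "polarity", "physical_contact"))
  expect_identical(tab$agent_id, "ID_himA")
  expect_identical(tab$patient_id, "ID_fimA")
})

test_that("flat key=value config files parse", {
  p <- tempfile()
  writeLines(c("# comment", "stopwords=which,that,who", "case_sensitive=TRUE"), p)
  cfg <- read_config(p)
  expect_identical(cfg$stopwords, c("which", "that", "who"))
  expect_identical(cfg$case_sensitive, "TRUE")
  writeLines("oops", p)
  expect_error(read_config(p), "malformed")
})
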