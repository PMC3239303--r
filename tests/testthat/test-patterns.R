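test_that("pattern parsing builds heads, roles, nesting and rejects unbound variables", {
  ont <- test_ontology()
  p4 <- parse_pattern(
    "(cause_Verb Subject:Agent Object:Patient)\t<RegulatoryProcess hasAgent=Agent hasPatient=Patient>",
    ont)
  expect_identical(p4$syn$lexeme, "cause")
  expect_identical(p4$syn$pos, "Verb")
  expect_identical(vapply(p4$syn$items, `[[`, "", "role"), c("Subject", "Object"))

  p2 <- parse_pattern(
    '(reduction_Noun (in_Prep Object:Patient))\t<RegulatoryProcess hasPatient=Patient hasPolarity="negative">',
    ont)
  expect_identical(p2$syn$items[[1]]$kind, "sub")
  expect_identical(p2$syn$items[[1]]$sub$lexeme, "in")
  expect_identical(p2$sem$slots$hasPolarity, "negative")

  expect_error(parse_pattern(
    "(cause_Verb Subject:Agent)\t<RegulatoryProcess hasAgent=Theme>", ont),
    "not bound")
  expect_error(parse_pattern("(cause_Verb Subject:Agent", ont), "tab")
  expect_error(parse_pattern(
    "(cause_Verb Badrole:Agent)\t<RegulatoryProcess hasAgent=Agent>", ont),
    "malformed dependent")
})

test_that("loose matching reaches non-direct descendants under the role subtree", {
  ## "expression of a fimA-lacZ fusion": fimA is not a direct child of 'of'
  ont <- test_ontology()
  lines <- c("1\texpression\texpression\tNOUN\t_\t_\t0\troot\t_\t_",
             "2\tof\tof\tADP\t_\t_\t1\tprep\t_\t_",
             "3\ta\ta\tDET\t_\t_\t5\tdet\t_\t_",
             "4\tfimA\tfimA\tNOUN\t_\t_\t5\tnn\t_\t_",
             "5\tfusion\tfusion\tNOUN\t_\t_\t2\tpobj\t_\t_", "")
  g <- read_conllu(lines)[[1]]
  ms <- recognize(g, him_dictionary())
  expect_length(ms, 1L)
  sems <- vector("list", 5L)
  sems[[4]] <- list(sem_entity("ID_fimA", "fimA", "Gene"))
  p1 <- test_patterns()[[1]]
  res <- match_at(p1, 1L, g, sems, ont)
  expect_length(res, 1L)
  expect_identical(res[[1]]$bindings$Gene$node, 4L)
  expect_identical(canonical_form(res[[1]]$struct),
                   "<GeneExpression hasPatient=@ID_fimA>")

  ## no Gene mention below: no match
  res2 <- match_at(p1, 1L, g, vector("list", 5L), ont)
  expect_length(res2, 0L)
})

test_that("clausal boundaries and exception words block the descendant path", {
  ont <- test_ontology()
  ## 'expression of the gene which ... fimA': fimA only reachable across 'which'
  lines <- c("1\texpression\texpression\tNOUN\t_\t_\t0\troot\t_\t_",
             "2\tof\tof\tADP\t_\t_\t1\tprep\t_\t_",
             "3\tgene\tgene\tNOUN\t_\t_\t2\tpobj\t_\t_",
             "4\twhich\twhich\tPRON\t_\t_\t5\tnsubj\t_\t_",
             "5\tprecedes\tprecede\tVERB\t_\t_\t3\trcmod\t_\t_",
             "6\tfimA\tfimA\tNOUN\t_\t_\t5\tdobj\t_\t_", "")
  g <- read_conllu(lines)[[1]]
  sems <- vector("list", 6L)
  sems[[6]] <- list(sem_entity("ID_fimA", "fimA", "Gene"))
  p1 <- test_patterns()[[1]]
  expect_length(match_at(p1, 1L, g, sems, ont), 0L)
  ## with a permissive control the same configuration matches
  res <- match_at(p1, 1L, g, sems, ont,
                  control = match_control(stopwords = character(0)))
  expect_length(res, 1L)
})

test_that("matching equals exhaustive assignment enumeration under conditions 1-3", {
  ont <- test_ontology()
  ctrl <- match_control()
  pat <- parse_pattern(
    "(cause_Verb Subject:Agent Object:Patient)\t<RegulatoryProcess hasAgent=Agent hasPatient=Patient>",
    ont)
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:8, 1L)
    lemmas <- c("cause", sample(c("alpha", "beta", "gamma", "which"), n - 1L,
                                replace = TRUE, prob = c(4, 4, 4, 1)))
    g <- random_tree(n, lemmas, upos = c("VERB", sample(c("NOUN", "ADP"),
                                                        n - 1L, replace = TRUE)))
    ## distinct entity semantics at every non-head node => no alternatives
    ## are collapsed and the full assignment set must be returned
    sems <- lapply(seq_len(n), function(i) {
      if (i == 1L) list() else list(sem_entity(paste0("ID_", i), paste0("e", i), "Gene"))
    })
    got <- match_at(pat, 1L, g, sems, ont, ctrl)
    got_pairs <- lapply(got, function(m) c(m$bindings$Agent$node, m$bindings$Patient$node))
    want_pairs <- oracle_two_item_assignments(g, 1L,
                                              c(ctrl$stopwords, ctrl$exceptions))
    key <- function(ps) sort(vapply(ps, paste, "", collapse = "-"))
    expect_identical(key(got_pairs), key(want_pairs))
  }
})

test_that("composition of the cascade sentence yields one four-instance event", {
  ex <- cascade_example()
  expect_length(ex$events, 1L)
  e <- ex$events[[1]]
  expect_identical(e$origin, "explicit")
  expect_identical(
    canonical_form(e$struct),
    paste0("<RegulatoryProcess hasAgent=<RegulatoryProcess hasPatient=@ID_himA",
           " hasPolarity=\"negative\"> hasPatient=<RegulatoryProcess",
           " hasPatient=<GeneExpression hasPatient=@ID_fimA>",
           " hasPolarity=\"negative\">>"))
  expect_true(sem_is_ground(e$struct))
})

test_that("coordinated conjuncts duplicate the assigned semantics", {
  ex <- cascade_example("coordination")
  lesions <- ex$semantics[[1]]
  structs <- Filter(is_sem_struct, lesions)
  expect_length(structs, 2L)
  ids <- sort(vapply(structs, function(s) sem_entity_ids(s), ""))
  expect_identical(ids, c("ID_himA", "ID_himD"))
  expect_length(ex$events, 2L)
})

test_that("a sentence without pattern matches composes no events", {
  ont <- test_ontology()
  g <- read_conllu(frame_sentence("distractor"))[[1]]
  expect_length(compose(g, list(), test_patterns(), ont), 0L)
})

test_that("every explicit event is ground and ontology-declared", {
  ont <- test_ontology()
  check_struct <- function(s) {
    if (is_sem_struct(s)) {
      expect_true(s$concept %in% ont$concepts)
      expect_true(all(names(s$slots) %in% ont$properties))
      lapply(s$slots, check_struct)
    }
    invisible(NULL)
  }
  for (frame in c("direct", "cascade", "coordination")) {
    ex <- cascade_example(frame)
    for (e in ex$events) {
      expect_true(sem_is_ground(e$struct))
      check_struct(e$struct)
    }
  }
})
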