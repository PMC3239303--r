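#' Configuration for the synthetic corpus generator
#'
#' The generator emits pre-parsed MEDLINE-abstract-like documents built from
#' fixed hand-written dependency-tree skeletons with gene/TF names substituted
#' in, together with the dictionary rows they use and gold annotations
#' (explicit events and final database records, each flagged with whether its
#' derivation needs the inference module).
#'
#' @param seed random seed; a fixed seed gives byte-identical output.
#' @param n_docs number of documents.
#' @param weights named non-negative frame mix weights over `direct`
#'   (X activates/represses the expression of Y; extractable without
#'   inference), `cascade` (lesions in X cause a reduction in expression of
#'   Y; needs the flattening rules), `coordination` (cascade with "X or X2"),
#'   `binding` (a regulation sentence plus a cross-sentence binding-site
#'   sentence; needs the evidence-combination rule), and `distractor` (no
#'   gold events). At least one weight must be positive.
#' @param tfs,genes synthetic name inventories for agents (transcription
#'   factors, carrying Gene/Protein/TranscriptionFactor labels) and patients
#'   (genes).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_docs = 10L,
                           weights = c(direct = 2, cascade = 2,
                                       coordination = 1, binding = 2,
                                       distractor = 1),
                           tfs = sprintf("TF%02d", 1:15),
                           genes = sprintf("G%04d", 1:40)) {
  frames <- c("direct", "cascade", "coordination", "binding", "distractor")
  w <- stats::setNames(numeric(length(frames)), frames)
  w[names(weights)] <- weights
  if (any(w < 0) || !any(w > 0)) {
    stop("frame weights must be non-negative with at least one positive",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 weights = w, tfs = tfs, genes = genes),
            class = "fixture_config")
}

grounding_id <- function(name) paste0("ID_", name)

#' Dictionary rows for fixture name inventories
#'
#' @param tfs,genes character name vectors.
#' @return data frame with columns `surface`, `id`, `labels`.
#' @export
make_dict_rows <- function(tfs = character(0), genes = character(0)) {
  rbind(
    if (length(tfs)) data.frame(surface = tfs, id = grounding_id(tfs),
                                labels = "Gene,Protein,TranscriptionFactor",
                                stringsAsFactors = FALSE),
    if (length(genes)) data.frame(surface = genes, id = grounding_id(genes),
                                  labels = "Gene", stringsAsFactors = FALSE)
  )
}

conllu_lines <- function(form, lemma, upos, head, deprel) {
  c(sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
            seq_along(form), form, lemma, upos, head, deprel), "")
}

#' Build the CoNLL-U block(s) for one fixture frame
#'
#' Dependency trees are fixed skeletons (Stanford-dependency style:
#' prepositions head their objects) with names substituted; they are what a
#' parser would plausibly produce for the frame sentences, chosen so that
#' gold derivations are exact.
#'
#' @param frame one of `direct`, `cascade`, `coordination`, `binding`,
#'   `distractor`.
#' @param agent,agent2,patient names substituted into the skeleton.
#' @param verb for `direct`: `"activates"` or `"represses"`.
#' @return character vector of CoNLL-U lines (one or two sentences).
#' @export
frame_sentence <- function(frame, agent = "himA", agent2 = "himD",
                           patient = "fimA", verb = "activates") {
  switch(
    frame,
    direct = {
      vlemma <- c(activates = "activate", represses = "repress")[[verb]]
      lemma <- c(agent, vlemma, "the", "expression", "of", patient, ".")
      conllu_lines(
        form = c(agent, verb, "the", "expression", "of", patient, "."),
        lemma = lemma,
        upos = c("NOUN", "VERB", "DET", "NOUN", "ADP", "NOUN", "PUNCT"),
        head = c(2L, 0L, 4L, 2L, 4L, 5L, 2L),
        deprel = c("nsubj", "root", "det", "dobj", "prep", "pobj", "punct"))
    },
    cascade = conllu_lines(
      form = c("lesions", "in", agent, "cause", "a", "reduction", "in",
               "expression", "of", patient, "."),
      lemma = c("lesion", "in", agent, "cause", "a", "reduction", "in",
                "expression", "of", patient, "."),
      upos = c("NOUN", "ADP", "NOUN", "VERB", "DET", "NOUN", "ADP",
               "NOUN", "ADP", "NOUN", "PUNCT"),
      head = c(4L, 1L, 2L, 0L, 6L, 4L, 6L, 7L, 8L, 9L, 4L),
      deprel = c("nsubj", "prep", "pobj", "root", "det", "dobj", "prep",
                 "pobj", "prep", "pobj", "punct")),
    coordination = conllu_lines(
      form = c("lesions", "in", agent, "or", agent2, "cause", "a",
               "reduction", "in", "expression", "of", patient, "."),
      lemma = c("lesion", "in", agent, "or", agent2, "cause", "a",
                "reduction", "in", "expression", "of", patient, "."),
      upos = c("NOUN", "ADP", "NOUN", "CCONJ", "NOUN", "VERB", "DET",
               "NOUN", "ADP", "NOUN", "ADP", "NOUN", "PUNCT"),
      head = c(6L, 1L, 2L, 5L, 3L, 0L, 8L, 6L, 8L, 9L, 10L, 11L, 6L),
      deprel = c("nsubj", "prep", "pobj", "cc", "conj", "root", "det",
                 "dobj", "prep", "pobj", "prep", "pobj", "punct")),
    binding = c(
      conllu_lines(
        form = c(agent, "regulates", "the", "expression", "of", patient, "."),
        lemma = c(agent, "regulate", "the", "expression", "of", patient, "."),
        upos = c("NOUN", "VERB", "DET", "NOUN", "ADP", "NOUN", "PUNCT"),
        head = c(2L, 0L, 4L, 2L, 4L, 5L, 2L),
        deprel = c("nsubj", "root", "det", "dobj", "prep", "pobj", "punct")),
      conllu_lines(
        form = c("the", "regulatory", "region", "of", patient, "contains",
                 "an", agent, "binding", "site", "."),
        lemma = c("the", "regulatory", "region", "of", patient, "contain",
                  "an", agent, "binding", "site", "."),
        upos = c("DET", "ADJ", "NOUN", "ADP", "NOUN", "VERB", "DET",
                 "NOUN", "NOUN", "NOUN", "PUNCT"),
        head = c(3L, 3L, 6L, 3L, 4L, 0L, 10L, 10L, 10L, 6L, 6L),
        deprel = c("det", "amod", "nsubj", "prep", "pobj", "root", "det",
                   "nn", "nn", "dobj", "punct"))),
    distractor = conllu_lines(
      form = c("the", "culture", "was", "grown", "overnight", "in", "rich",
               "medium", "."),
      lemma = c("the", "culture", "be", "grow", "overnight", "in", "rich",
                "medium", "."),
      upos = c("DET", "NOUN", "AUX", "VERB", "ADV", "ADP", "ADJ", "NOUN",
               "PUNCT"),
      head = c(2L, 4L, 4L, 0L, 4L, 4L, 8L, 6L, 4L),
      deprel = c("det", "nsubjpass", "auxpass", "root", "advmod", "prep",
                 "amod", "pobj", "punct")),
    stop("unknown frame '", frame, "'", call. = FALSE)
  )
}

## Gold final records for one frame instance (participants by grounding id).
frame_gold <- function(frame, doc, agent, agent2, patient, verb) {
  rec <- function(template, type, a, p, pol, contact, inf) {
    data.frame(doc = doc, template = template, type = type,
               agent_id = grounding_id(a), patient_id = grounding_id(p),
               polarity = pol, physical_contact = contact,
               requires_inference = inf, stringsAsFactors = FALSE)
  }
  switch(
    frame,
    direct = rec("T1", "RegulationOfGeneExpression", agent, patient,
                 if (verb == "represses") "negative" else "positive",
                 "no", FALSE),
    cascade = rec("T1", "RegulationOfGeneExpression", agent, patient,
                  "positive", "no", TRUE),
    coordination = rbind(
      rec("T1", "RegulationOfGeneExpression", agent, patient, "positive", "no", TRUE),
      rec("T1", "RegulationOfGeneExpression", agent2, patient, "positive", "no", TRUE)),
    binding = rbind(
      rec("T1", "RegulationOfGeneExpression", agent, patient, "unknown", "no", TRUE),
      rec("T2", "RegulationOfTranscription", agent, patient, "unknown", "yes", TRUE)),
    distractor = NULL
  )
}

## Canonical forms of the explicit events the frame's sentences express.
frame_gold_explicit <- function(frame, agent, agent2, patient, verb) {
  ent <- function(nm, tf) sem_entity(grounding_id(nm), nm,
                                     if (tf) c("Gene", "Protein", "TranscriptionFactor") else "Gene")
  ge <- function(p) sem_struct("GeneExpression", list(hasPatient = ent(p, FALSE)))
  casc <- function(a, p) sem_struct("RegulatoryProcess", list(
    hasAgent = sem_struct("RegulatoryProcess",
                          list(hasPatient = ent(a, TRUE), hasPolarity = "negative")),
    hasPatient = sem_struct("RegulatoryProcess",
                            list(hasPatient = ge(p), hasPolarity = "negative"))))
  structs <- switch(
    frame,
    direct = list(sem_struct("RegulationOfGeneExpression", list(
      hasAgent = ent(agent, TRUE), hasPatient = ge(patient),
      hasPolarity = if (verb == "represses") "negative" else "positive"))),
    cascade = list(casc(agent, patient)),
    coordination = list(casc(agent, patient), casc(agent2, patient)),
    binding = list(
      sem_struct("RegulatoryProcess", list(hasAgent = ent(agent, TRUE),
                                           hasPatient = ge(patient))),
      sem_struct("RegulatoryDNARegion", list(
        hasAgent = ent(patient, FALSE),
        hasPart = sem_struct("TranscriptionFactorBindingSiteOfDNA",
                             list(hasAgent = ent(agent, TRUE)))))),
    distractor = list()
  )
  vapply(structs, canonical_form, "")
}

#' Generate a synthetic gold-annotated corpus
#'
#' Deterministic under the configuration seed. Each document carries its
#' CoNLL-U text, the dictionary rows it uses, the canonical forms of its gold
#' explicit events, and its gold final records flagged with
#' `requires_inference` (whether the record is derivable without the closure
#' step), so the full pipeline and the with/without-inference ablation can be
#' scored exactly.
#'
#' @param config a [fixture_config()].
#' @return list of `gold_document` objects.
#' @export
generate_fixtures <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  frames <- names(config$weights)[config$weights > 0]
  probs <- config$weights[config$weights > 0]
  lapply(seq_len(config$n_docs), function(i) {
    doc <- sprintf("doc%03d", i)
    frame <- sample(frames, 1L, prob = probs)
    tf2 <- sample(config$tfs, 2L)
    agent <- tf2[[1]]; agent2 <- tf2[[2]]
    patient <- sample(config$genes, 1L)
    verb <- sample(c("activates", "represses"), 1L)
    dict_rows <- switch(frame,
                        distractor = make_dict_rows(),
                        coordination = rbind(make_dict_rows(tfs = c(agent, agent2)),
                                             make_dict_rows(genes = patient)),
                        rbind(make_dict_rows(tfs = agent),
                              make_dict_rows(genes = patient)))
    structure(list(
      doc = doc, frame = frame,
      conllu = frame_sentence(frame, agent, agent2, patient, verb),
      dict_rows = dict_rows,
      gold_explicit = frame_gold_explicit(frame, agent, agent2, patient, verb),
      gold_records = frame_gold(frame, doc, agent, agent2, patient, verb)
    ), class = "gold_document")
  })
}

#' Combined gold-record table of a fixture corpus
#'
#' @param fixdocs list of `gold_document`s.
#' @return data frame (zero rows when no document has gold records).
#' @export
gold_records <- function(fixdocs) {
  recs <- Filter(Negate(is.null), lapply(fixdocs, `[[`, "gold_records"))
  if (length(recs) == 0L) {
    return(data.frame(doc = character(0), template = character(0),
                      type = character(0), agent_id = character(0),
                      patient_id = character(0), polarity = character(0),
                      physical_contact = character(0),
                      requires_inference = logical(0)))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write a fixture corpus to disk
#'
#' Writes one CoNLL-U file per document, the combined `dictionary.tsv`, the
#' gold annotations as `gold.json`, and a `config.txt` echo.
#'
#' @param fixdocs list of `gold_document`s from [generate_fixtures()].
#' @param dir output directory.
#' @param config the generating [fixture_config()] (echoed for provenance).
#' @return named character vector of document CoNLL-U paths, invisibly.
#' @export
write_fixtures <- function(fixdocs, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (fd in fixdocs) {
    p <- file.path(dir, paste0(fd$doc, ".conllu"))
    writeLines(fd$conllu, p)
    paths[[fd$doc]] <- p
  }
  dict <- unique(do.call(rbind, c(lapply(fixdocs, `[[`, "dict_rows"),
                                  list(make_dict_rows()))))
  if (is.null(dict)) {
    writeLines(character(0), file.path(dir, "dictionary.tsv"))
  } else {
    utils::write.table(dict, file.path(dir, "dictionary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  gold <- lapply(fixdocs, function(fd) {
    list(doc = fd$doc, frame = fd$frame,
         gold_explicit = as.list(fd$gold_explicit),
         gold_records = fd$gold_records)
  })
  jsonlite::write_json(gold, file.path(dir, "gold.json"), auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(config)) {
    writeLines(c(sprintf("seed=%d", config$seed),
                 sprintf("n_docs=%d", config$n_docs),
                 sprintf("weights=%s", paste(sprintf("%s:%g", names(config$weights),
                                                     config$weights), collapse = ","))),
               file.path(dir, "config.txt"))
  }
  invisible(paths)
}

#' Dictionary and documents of a fixture corpus, ready for the pipeline
#'
#' Convenience wrapper: loads the corpus as in-memory graphs plus a validated
#' dictionary, without touching disk.
#'
#' @param fixdocs list of `gold_document`s.
#' @param ont a `gro_ontology`.
#' @return list with `docs` (named list of graph lists) and `dict`.
#' @export
fixture_corpus <- function(fixdocs, ont = load_ontology()) {
  docs <- lapply(fixdocs, function(fd) read_conllu(fd$conllu))
  names(docs) <- vapply(fixdocs, `[[`, "", "doc")
  dict_df <- unique(do.call(rbind, c(lapply(fixdocs, `[[`, "dict_rows"),
                                     list(make_dict_rows()))))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  if (is.null(dict_df) || nrow(dict_df) == 0L) {
    writeLines(character(0), tmp)
  } else {
    utils::write.table(dict_df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(docs = docs, dict = load_dictionary(tmp, ont))
}
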