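#' Run the full extraction pipeline
#'
#' For each document: read the CoNLL-U dependency trees, recognize entity
#' mentions, compose explicit events bottom-up with the patterns, optionally
#' close the document's events under the inference rules (closure scope is the
#' whole document, so evidence from different sentences combines), and match
#' the semantic templates to emit database records.
#'
#' @param docs named character vector of CoNLL-U file paths (names are
#'   document ids), or a named list of pre-read `dep_graph` lists.
#' @param dict an `entity_dictionary`.
#' @param ont a `gro_ontology`.
#' @param patterns list of `pattern_pair`s.
#' @param rules list of `inference_rule`s.
#' @param templates list of `event_template`s.
#' @param inference apply the inference module (`FALSE` reproduces the
#'   pattern-matching-only ablation).
#' @param control a [match_control()].
#' @param tagmap tag map for [read_conllu()] (file-path input only).
#' @param verbose log per-document counts to stderr.
#' @return list of class `regevents_result`: `events`, `records` (data
#'   frame), `mentions`, and per-document `graphs`.
#' @export
run_pipeline <- function(docs, dict, ont,
                         patterns = load_patterns(ont = ont),
                         rules = load_rules(ont = ont),
                         templates = load_templates(ont = ont),
                         inference = TRUE, control = match_control(),
                         tagmap = default_tagmap(), verbose = FALSE) {
  if (is.null(names(docs)) || any(!nzchar(names(docs)))) {
    names(docs) <- sprintf("doc%03d", seq_along(docs))
  }
  all_events <- list()
  all_mentions <- list()
  all_records <- list()
  all_graphs <- list()
  for (doc in names(docs)) {
    graphs <- if (is.character(docs)) read_conllu(docs[[doc]], tagmap) else docs[[doc]]
    mentions <- list()
    events <- list()
    for (g in graphs) {
      ms <- recognize(g, dict, doc = doc)
      mentions <- c(mentions, ms)
      events <- c(events, compose(g, ms, patterns, ont, control, doc = doc))
    }
    if (inference) events <- closure(events, rules, ont)
    records <- extract_records(events, templates, ont)
    if (nrow(records)) records$event <- records$event + length(all_events)
    if (verbose) {
      message(sprintf("%s: %d sentences, %d mentions, %d events (%d inferred), %d records",
                      doc, length(graphs), length(mentions), length(events),
                      sum(vapply(events, `[[`, "", "origin") == "inferred"),
                      nrow(records)))
    }
    all_graphs[[doc]] <- graphs
    all_mentions <- c(all_mentions, mentions)
    all_events <- c(all_events, events)
    all_records[[length(all_records) + 1L]] <- records
  }
  records <- if (length(all_records)) do.call(rbind, all_records) else empty_records()
  rownames(records) <- NULL
  structure(list(events = all_events, records = records,
                 mentions = all_mentions, graphs = all_graphs),
            class = "regevents_result")
}

#' @export
print.regevents_result <- function(x, ...) {
  origins <- vapply(x$events, `[[`, "", "origin")
  cat("<regevents_result> ", length(x$graphs), " document(s), ",
      length(x$mentions), " mentions, ", sum(origins == "explicit"),
      " explicit + ", sum(origins == "inferred"), " inferred events, ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}
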