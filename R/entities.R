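#' Load an entity dictionary
#'
#' Tab-separated file with three columns: surface form, grounding identifier,
#' and a comma-separated list of ontology concept labels (e.g.
#' `fimA<TAB>P04128<TAB>Gene`). One surface form may carry several labels —
#' gene/protein metonymy is expressed by listing `Gene,Protein` (or
#' `TranscriptionFactor`) on the same entry; downstream concept constraints
#' succeed if any label satisfies them.
#'
#' @param path TSV file path.
#' @param ont a `gro_ontology`; every concept label must be declared in it.
#' @return An object of class `entity_dictionary`.
#' @export
load_dictionary <- function(path, ont) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  entries <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L || !nzchar(f[[1]])) {
      stop("dictionary row ", i, " malformed: '", lines[[i]], "'", call. = FALSE)
    }
    labels <- trimws(strsplit(f[[3]], ",", fixed = TRUE)[[1]])
    for (l in labels) {
      if (!concept_declared(ont, l)) {
        stop("dictionary row ", i, ": unknown concept '", l, "'", call. = FALSE)
      }
    }
    entries[[f[[1]]]] <- list(id = f[[2]],
                              labels = vapply(labels, resolve_concept, "", ont = ont,
                                              USE.NAMES = FALSE))
  }
  structure(list(entries = entries,
                 max_tokens = if (length(entries)) {
                   max(lengths(strsplit(names(entries), " ", fixed = TRUE)))
                 } else 0L),
            class = "entity_dictionary")
}

#' Dictionary-based named entity recognition
#'
#' Scans a sentence left to right with longest-match-first lookup over
#' contiguous token windows; matches never overlap. Matching is token-level
#' and case-sensitive by default (short gene symbols are case-meaningful).
#'
#' @param graph a `dep_graph`.
#' @param dict an `entity_dictionary`.
#' @param doc document identifier carried into the mentions.
#' @param case_sensitive lower-case both sides before lookup when `FALSE`.
#' @return list of `entity_mention` objects: token span (half-open), surface
#'   text, grounding id, concept labels, character offsets, and the span's
#'   syntactic head token.
#' @export
recognize <- function(graph, dict, doc = "doc1", case_sensitive = TRUE) {
  toks <- graph$tokens
  keys <- names(dict$entries)
  lookup <- dict$entries
  if (!case_sensitive) names(lookup) <- tolower(keys)
  forms <- if (case_sensitive) toks$form else tolower(toks$form)
  n <- nrow(toks)
  mentions <- list()
  if (dict$max_tokens == 0L) return(mentions)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(dict$max_tokens, n - i + 1L), 1L)) {
      key <- paste(forms[i:(i + len - 1L)], collapse = " ")
      if (!is.null(lookup[[key]])) { hit <- list(len = len, entry = lookup[[key]]); break }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    span <- i:(i + hit$len - 1L)
    head_tok <- span[!toks$head[span] %in% span]
    head_tok <- if (length(head_tok)) head_tok[[1]] else span[[1]]
    mentions[[length(mentions) + 1L]] <- structure(list(
      doc = doc, sentence = graph$sentence,
      start = i, end = i + hit$len,
      surface = paste(toks$form[span], collapse = " "),
      id = hit$entry$id, labels = hit$entry$labels,
      char_start = toks$start[span[[1]]], char_end = toks$end[span[[length(span)]]],
      head = head_tok
    ), class = "entity_mention")
    i <- i + hit$len
  }
  mentions
}

#' @export
print.entity_mention <- function(x, ...) {
  cat(sprintf("<mention> %s [%s] %s tokens %d-%d (sent %d)\n",
              x$surface, x$id, paste(x$labels, collapse = ","),
              x$start, x$end - 1L, x$sentence))
  invisible(x)
}

## Atomic semantic value seeded at a mention's head token.
mention_entity <- function(m) {
  e <- sem_entity(m$id, m$surface, m$labels)
  attr(e, "mention") <- m
  e
}
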