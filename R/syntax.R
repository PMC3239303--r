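#' Default part-of-speech and relation normalization
#'
#' Maps parser tags onto the coarse vocabulary used by the pattern language:
#' coarse POS `Verb`, `Noun`, `Prep`, `Adj`, `Other` and syntactic roles
#' `Subject`, `Object`, `PrepObject`, `Conj`, `Other`. Unknown tags map to
#' `Other`. Input is expected in a dependency style where prepositions head
#' their objects (`prep`/`pobj`, Stanford-dependency style), matching the
#' `Prep`-headed items of the pattern language; UD-style `obj`/`obl` labels
#' are mapped as well.
#'
#' @param path optional two-column whitespace-separated file
#'   (`tag normalized`) extending or overriding the defaults; entries whose
#'   normalized value is a role name extend the relation map, all others the
#'   POS map.
#' @return list with character maps `pos` and `rel`.
#' @export
default_tagmap <- function(path = NULL) {
  pos <- c(VERB = "Verb", AUX = "Verb",
           NOUN = "Noun", PROPN = "Noun", PRON = "Noun",
           ADP = "Prep", IN = "Prep",
           ADJ = "Adj",
           NN = "Noun", NNS = "Noun", NNP = "Noun",
           VB = "Verb", VBD = "Verb", VBZ = "Verb", VBN = "Verb", VBG = "Verb",
           JJ = "Adj")
  rel <- c(nsubj = "Subject", nsubjpass = "Subject", "nsubj:pass" = "Subject",
           csubj = "Subject",
           dobj = "Object", obj = "Object", iobj = "Object",
           pobj = "PrepObject", obl = "PrepObject", nmod = "PrepObject",
           conj = "Conj")
  if (!is.null(path)) {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("tag", "norm"))
    roles <- c("Subject", "Object", "PrepObject", "Conj", "Other")
    for (i in seq_len(nrow(tab))) {
      if (tab$norm[i] %in% roles) rel[tab$tag[i]] <- tab$norm[i] else pos[tab$tag[i]] <- tab$norm[i]
    }
  }
  list(pos = pos, rel = rel)
}

map_or_other <- function(map, tags, allowed) {
  out <- unname(map[tags])
  out[is.na(out)] <- "Other"
  out[!out %in% allowed] <- "Other"
  out
}

#' Read CoNLL-U input into dependency graphs
#'
#' One blank-line-separated block per sentence; `#` comment lines are skipped;
#' multiword-token (`1-2`) and empty-node (`1.1`) rows are dropped. Each
#' sentence must have contiguous 1-based token indices, exactly one root
#' (`HEAD == 0`) and acyclic head links. Character offsets are assigned by
#' joining tokens with single spaces and sentences with newlines, so that
#' standoff output can reference a reconstructed document text.
#'
#' @param x a file path, or a character vector of CoNLL-U lines.
#' @param tagmap a tag map from [default_tagmap()].
#' @return list of `dep_graph` objects; the reconstructed document text is
#'   attached as attribute `"text"`.
#' @export
read_conllu <- function(x, tagmap = default_tagmap()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- c(lines, "")
  graphs <- list()
  block <- list()
  offset <- 0L
  sent <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (nzchar(trimws(ln))) {
      if (!startsWith(ln, "#")) block[[length(block) + 1L]] <- ln
      next
    }
    if (length(block) == 0L) next
    sent <- sent + 1L
    g <- parse_conllu_block(block, sent, tagmap, offset)
    offset <- max(g$tokens$end) + 1L  # newline between sentences
    graphs[[sent]] <- g
    block <- list()
  }
  text <- paste(vapply(graphs, function(g) paste(g$tokens$form, collapse = " "), ""),
                collapse = "\n")
  attr(graphs, "text") <- text
  graphs
}

parse_conllu_block <- function(block, sent, tagmap, offset) {
  rows <- lapply(block, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  keep <- vapply(rows, function(r) grepl("^[0-9]+$", r[[1]]), TRUE)
  rows <- rows[keep]
  if (length(rows) == 0L) stop("sentence ", sent, ": no token rows", call. = FALSE)
  bad <- vapply(rows, length, 0L) < 8L
  if (any(bad)) {
    stop("sentence ", sent, ": malformed line '",
         paste(rows[[which(bad)[1]]], collapse = "\t"), "'", call. = FALSE)
  }
  id <- vapply(rows, function(r) as.integer(r[[1]]), 0L)
  if (!identical(id, seq_along(id))) {
    stop("sentence ", sent, ": token indices not contiguous from 1", call. = FALSE)
  }
  form <- vapply(rows, `[[`, "", 2L)
  lemma <- vapply(rows, `[[`, "", 3L)
  lemma[lemma == "_"] <- form[lemma == "_"]
  upos <- vapply(rows, `[[`, "", 4L)
  head <- suppressWarnings(vapply(rows, function(r) as.integer(r[[7]]), 0L))
  if (anyNA(head)) stop("sentence ", sent, ": non-numeric HEAD field", call. = FALSE)
  deprel <- vapply(rows, `[[`, "", 8L)
  if (sum(head == 0L) != 1L) {
    stop("sentence ", sent, ": expected exactly one root, found ",
         sum(head == 0L), call. = FALSE)
  }
  if (any(head > length(id) | head < 0L)) {
    stop("sentence ", sent, ": HEAD index out of range", call. = FALSE)
  }
  ## cycle check: every token must reach the root by following heads
  for (v in id) {
    seen <- logical(length(id))
    u <- v
    while (u != 0L) {
      if (seen[u]) stop("sentence ", sent, ": cyclic head links involving token ", u, call. = FALSE)
      seen[u] <- TRUE
      u <- head[u]
    }
  }
  start <- offset + c(0L, cumsum(nchar(form) + 1L))[seq_along(form)]
  tokens <- data.frame(
    id = id, form = form, lemma = lemma, upos = upos,
    pos = map_or_other(tagmap$pos, upos, c("Verb", "Noun", "Prep", "Adj", "Other")),
    head = head, deprel = deprel,
    role = map_or_other(tagmap$rel, deprel,
                        c("Subject", "Object", "PrepObject", "Conj", "Other")),
    start = start, end = start + nchar(form),
    stringsAsFactors = FALSE
  )
  structure(list(sentence = sent, tokens = tokens), class = "dep_graph")
}

#' Write dependency graphs back to CoNLL-U
#'
#' @param graphs list of `dep_graph` objects.
#' @param path optional output file; if `NULL` the lines are returned.
#' @return character vector of lines, invisibly when written to a file.
#' @export
write_conllu <- function(graphs, path = NULL) {
  out <- unlist(lapply(graphs, function(g) {
    t <- g$tokens
    c(sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
              t$id, t$form, t$lemma, t$upos, t$head, t$deprel), "")
  }), use.names = FALSE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

children_of <- function(graph, node) graph$tokens$id[graph$tokens$head == node]

#' Strict descendants of a node
#'
#' Breadth-first: ordered by tree depth ascending, then surface position.
#'
#' @param graph a `dep_graph`.
#' @param node 1-based token index.
#' @return integer vector of descendant token indices (possibly empty).
#' @export
descendants <- function(graph, node) {
  if (!node %in% graph$tokens$id) stop("unknown node ", node, call. = FALSE)
  out <- integer(0)
  frontier <- sort(children_of(graph, node))
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- sort(unlist(lapply(frontier, children_of, graph = graph), use.names = FALSE))
  }
  out
}

## Downward path from `anc` to `desc`, excluding `anc`, including `desc`.
## NULL if `desc` is not a descendant of `anc`.
path_down <- function(graph, anc, desc) {
  head <- graph$tokens$head
  path <- integer(0)
  u <- desc
  while (u != 0L && u != anc) {
    path <- c(u, path)
    u <- head[u]
  }
  if (u == anc) path else NULL
}

#' @export
print.dep_graph <- function(x, ...) {
  cat("<dep_graph> sentence ", x$sentence, ": ",
      paste(x$tokens$form, collapse = " "), "\n", sep = "")
  invisible(x)
}
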