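#' Matching control options
#'
#' Loose matching may bind a pattern's dependent item to any descendant of the
#' head-matched node, but the head-to-dependent path must not cross a clausal
#' boundary (relative pronouns, complementizers) nor an exception word. Both
#' word lists are configurable.
#'
#' @param stopwords clausal-boundary lemmas.
#' @param exceptions exception lemmas.
#' @param negation negation cue lemmas; matches whose head-to-dependent paths
#'   or head nodes carry a cue are still produced, but flagged in provenance.
#' @return list of class `match_control`.
#' @export
match_control <- function(stopwords = c("which", "that", "who", "whose",
                                        "when", "where", "because", "although"),
                          exceptions = c("except", "unless", "without"),
                          negation = c("not", "no", "never", "fail")) {
  structure(list(stopwords = stopwords, exceptions = exceptions,
                 negation = negation),
            class = "match_control")
}

POS_TAGS <- c("Verb", "Noun", "Prep", "Adj", "Other")
ROLE_TAGS <- c("Subject", "Object", "PrepObject")

## ---- pattern DSL -----------------------------------------------------------

#' Parse a syntactic-semantic paired pattern
#'
#' A pattern line has a syntactic part and a semantic part separated by a tab,
#' e.g. `(cause_Verb Subject:Agent Object:Patient)` paired with
#' `<RegulatoryProcess hasAgent=Agent hasPatient=Patient>`. The leftmost item
#' in a parenthesis is the head (`lexeme_POS`); dependent items are
#' `Role:Variable` pairs, bare variables, bare `lexeme_POS` function words, or
#' nested parenthesized sub-patterns. A variable whose name is a declared
#' concept is constrained to bind semantics of that concept or a subconcept.
#' Every variable of the semantic part must be bound by a syntactic item.
#'
#' @param text one `SYNTACTIC<TAB>SEMANTIC` line (an optional leading third
#'   field gives the pattern id).
#' @param ont a `gro_ontology`.
#' @param id pattern identifier used when the line carries none.
#' @return An object of class `pattern_pair`.
#' @export
parse_pattern <- function(text, ont, id = "P1") {
  fields <- strsplit(text, "\t", fixed = TRUE)[[1]]
  fields <- fields[nzchar(trimws(fields))]
  if (length(fields) == 3L) {
    id <- trimws(fields[[1]]); fields <- fields[2:3]
  }
  if (length(fields) != 2L) {
    stop("pattern line must have syntactic and semantic parts separated by a tab",
         call. = FALSE)
  }
  syn <- parse_syn(trimws(fields[[1]]), ont)
  sem <- parse_sem(trimws(fields[[2]]), ont, allow_vars = TRUE, allow_calls = FALSE)
  svars <- syn_vars(syn)
  if (anyDuplicated(svars)) {
    stop("pattern ", id, ": duplicate variable '",
         svars[duplicated(svars)][1], "' in syntactic part", call. = FALSE)
  }
  unbound <- setdiff(sem_vars(sem), svars)
  if (length(unbound)) {
    stop("pattern ", id, ": semantic variable(s) not bound syntactically: ",
         paste(unbound, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, syn = syn, sem = sem), class = "pattern_pair")
}

parse_syn <- function(text, ont) {
  toks <- syn_tokenize(text)
  st <- new.env(parent = emptyenv()); st$tokens <- toks; st$i <- 1L
  node <- parse_syn_node(st, ont)
  if (st$i <= length(st$tokens)) stop("trailing input in syntactic pattern", call. = FALSE)
  node
}

syn_tokenize <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

parse_syn_node <- function(st, ont) {
  if (syn_next(st) != "(") stop("expected '(' in syntactic pattern", call. = FALSE)
  head <- syn_next(st)
  hp <- split_lex_pos(head)
  if (is.null(hp)) stop("pattern head '", head, "' must be lexeme_POS", call. = FALSE)
  items <- list()
  repeat {
    tok <- syn_peek(st)
    if (is.null(tok)) stop("unterminated '(' in syntactic pattern", call. = FALSE)
    if (tok == ")") { st$i <- st$i + 1L; break }
    if (tok == "(") {
      items[[length(items) + 1L]] <- list(kind = "sub", role = NA_character_,
                                          sub = parse_syn_node(st, ont))
      next
    }
    st$i <- st$i + 1L
    role <- NA_character_
    body <- tok
    if (grepl(":", tok, fixed = TRUE)) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !parts[[1]] %in% ROLE_TAGS) {
        stop("malformed dependent item '", tok, "'", call. = FALSE)
      }
      role <- parts[[1]]; body <- parts[[2]]
    }
    lp <- split_lex_pos(body)
    if (!is.null(lp)) {
      items[[length(items) + 1L]] <- list(kind = "lex", role = role,
                                          lexeme = lp$lexeme, pos = lp$pos)
    } else {
      concept <- NA_character_
      name <- body
      if (concept_declared(ont, name)) {
        concept <- resolve_concept(ont, name); name <- concept
      }
      items[[length(items) + 1L]] <- list(kind = "var", role = role,
                                          var = name, concept = concept)
    }
  }
  list(lexeme = hp$lexeme, pos = hp$pos, items = items)
}

syn_peek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
syn_next <- function(st) { tok <- syn_peek(st); if (!is.null(tok)) st$i <- st$i + 1L; tok }

split_lex_pos <- function(tok) {
  m <- regmatches(tok, regexec("^(.+)_(Verb|Noun|Prep|Adj|Other)$", tok))[[1]]
  if (length(m) == 3L) list(lexeme = m[[2]], pos = m[[3]]) else NULL
}

syn_vars <- function(node) {
  unlist(lapply(node$items, function(it) {
    switch(it$kind, var = it$var, sub = syn_vars(it$sub), character(0))
  }), use.names = FALSE)
}

#' Load a pattern file
#'
#' One pattern per line (`#` comments and blank lines ignored); ids are taken
#' from an optional leading field or assigned positionally.
#'
#' @param path pattern file; defaults to the patterns shipped with the package.
#' @param ont a `gro_ontology`.
#' @return list of `pattern_pair` objects.
#' @export
load_patterns <- function(path = system.file("extdata", "patterns.tsv",
                                             package = "regevents"),
                          ont = load_ontology()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    parse_pattern(lines[[i]], ont, id = sprintf("P%02d", i))
  })
}

#' @export
print.pattern_pair <- function(x, ...) {
  cat("<pattern_pair> ", x$id, ": ", format_syn(x$syn), "  ->  ",
      canonical_form(x$sem), "\n", sep = "")
  invisible(x)
}

format_syn <- function(node) {
  items <- vapply(node$items, function(it) {
    body <- switch(it$kind,
                   sub = format_syn(it$sub),
                   lex = paste0(it$lexeme, "_", it$pos),
                   var = it$var)
    if (!is.na(it$role)) paste0(it$role, ":", body) else body
  }, "")
  paste0("(", paste(c(paste0(node$lexeme, "_", node$pos), items), collapse = " "), ")")
}

## ---- loose matching --------------------------------------------------------

role_satisfied <- function(node_role, wanted) {
  switch(wanted,
         Subject = node_role == "Subject",
         Object = node_role %in% c("Object", "PrepObject"),
         PrepObject = node_role == "PrepObject",
         FALSE)
}

## Eligibility of descendant `d` for an item of a pattern headed at `node`:
## condition 3 (no clausal boundary or exception lemma strictly between the
## two) and condition 1 (some node on the head-exclusive, candidate-inclusive
## path bears the required syntactic role).
path_eligible <- function(graph, node, d, role, control) {
  path <- path_down(graph, node, d)
  if (is.null(path)) return(FALSE)
  between <- path[-length(path)]
  if (length(between)) {
    ## a clause boundary is crossed when an intermediate node is (or carries,
    ## as a direct child, e.g. a relativizer attached to its clause head) a
    ## boundary or exception word
    marked <- unique(c(between,
                       unlist(lapply(between, children_of, graph = graph),
                              use.names = FALSE)))
    lem <- tolower(graph$tokens$lemma[marked])
    if (any(lem %in% c(control$stopwords, control$exceptions))) return(FALSE)
  }
  if (!is.na(role)) {
    roles <- graph$tokens$role[path]
    if (!any(vapply(roles, role_satisfied, TRUE, wanted = role))) return(FALSE)
  }
  TRUE
}

head_matches <- function(graph, node, lexeme, pos) {
  tolower(graph$tokens$lemma[node]) == tolower(lexeme) &&
    graph$tokens$pos[node] == pos
}

## Core matcher over entry lists (entries carry uid/signature for consumption
## tracking and alternative collapsing). Returns list of matches:
## list(bindings = var -> list(node, entry), item_nodes = list of int vectors).
match_syn_at <- function(syn, node, graph, semx, ont, control) {
  if (!head_matches(graph, node, syn$lexeme, syn$pos)) return(list())
  desc <- descendants(graph, node)
  per_item <- vector("list", length(syn$items))
  for (k in seq_along(syn$items)) {
    it <- syn$items[[k]]
    cands <- list()
    for (d in desc) {
      if (!path_eligible(graph, node, d, it$role, control)) next
      dep <- length(path_down(graph, node, d))
      if (it$kind == "lex") {
        if (!head_matches(graph, d, it$lexeme, it$pos)) next
        cands[[length(cands) + 1L]] <- list(bindings = list(), nodes = d,
                                            sig = "", depth = dep, pos = d, ord = 0L)
      } else if (it$kind == "var") {
        entries <- semx[[d]]
        for (entry in entries) {
          ok <- if (is.na(it$concept)) TRUE else {
            value_under_concept(ont, entry$struct, it$concept)
          }
          if (!ok) next
          cands[[length(cands) + 1L]] <- list(
            bindings = stats::setNames(list(list(node = d, entry = entry)), it$var),
            nodes = d, sig = entry$sig, depth = dep, pos = d, ord = entry$uid)
        }
      } else {  # nested sub-pattern
        subs <- match_syn_at(it$sub, d, graph, semx, ont, control)
        for (sm in subs) {
          sig <- paste(sort(unique(unlist(lapply(sm$bindings, function(b) b$entry$sig)))),
                       collapse = "|")
          cands[[length(cands) + 1L]] <- list(
            bindings = sm$bindings, nodes = c(d, unlist(sm$item_nodes)),
            sig = sig, depth = dep, pos = d, ord = 0L)
        }
      }
    }
    if (length(cands) == 0L) return(list())
    ## tie-break: minimal depth, then leftmost; alternatives kept only when
    ## they involve a distinct set of bound mentions
    ord <- order(vapply(cands, `[[`, 0L, "depth"),
                 vapply(cands, `[[`, 0L, "pos"),
                 vapply(cands, `[[`, 0L, "ord"))
    cands <- cands[ord]
    sigs <- vapply(cands, `[[`, "", "sig")
    per_item[[k]] <- cands[!duplicated(sigs)]
  }
  ## combine items (Cartesian product), enforcing condition 2: no item's
  ## matched node may dominate (or equal) another item's matched node
  acc <- list(list(bindings = list(), item_nodes = list()))
  for (k in seq_along(per_item)) {
    nxt <- list()
    for (a in acc) {
      for (cand in per_item[[k]]) {
        ok <- TRUE
        for (prev in a$item_nodes) {
          if (nodes_overlap(graph, prev, cand$nodes)) { ok <- FALSE; break }
        }
        if (!ok) next
        nxt[[length(nxt) + 1L]] <- list(
          bindings = c(a$bindings, cand$bindings),
          item_nodes = c(a$item_nodes, list(cand$nodes)))
      }
    }
    acc <- nxt
    if (length(acc) == 0L) return(list())
  }
  acc
}

nodes_overlap <- function(graph, xs, ys) {
  for (x in xs) {
    dx <- c(x, descendants(graph, x))
    if (any(ys %in% dx)) return(TRUE)
  }
  for (y in ys) {
    dy <- c(y, descendants(graph, y))
    if (any(xs %in% dy)) return(TRUE)
  }
  FALSE
}

#' Match one pattern at one node
#'
#' Applies the loose-matching algorithm for a single pattern at a single node,
#' given the semantics already available for the node's strict descendants
#' (bottom-up discipline): the head lexeme/POS must match the node at lemma
#' level, and each dependent item is matched to a descendant subject to the
#' three conditions — role-subtree confinement, no re-use of a matched node's
#' descendants by other items, and no crossing of clausal boundaries or
#' exception words.
#'
#' @param pattern a `pattern_pair`.
#' @param node token index.
#' @param graph a `dep_graph`.
#' @param semantics list (token index -> list of semantic values) covering the
#'   node's strict descendants.
#' @param ont a `gro_ontology`.
#' @param control a [match_control()].
#' @return list of match results, each with `pattern`, `head`, `bindings`
#'   (variable -> list of `node` and `value`) and the instantiated `struct`.
#' @export
match_at <- function(pattern, node, graph, semantics, ont,
                     control = match_control()) {
  semx <- vector("list", nrow(graph$tokens))
  uid <- 0L
  for (i in seq_along(semantics)) {
    vals <- semantics[[i]]
    semx[[i]] <- lapply(vals, function(v) {
      uid <<- uid + 1L
      list(struct = v, sig = paste(sem_entity_ids(v), collapse = ","), uid = uid)
    })
  }
  ms <- match_syn_at(pattern$syn, node, graph, semx, ont, control)
  lapply(ms, function(m) {
    vals <- lapply(m$bindings, function(b) b$entry$struct)
    list(pattern = pattern$id, head = node,
         bindings = lapply(m$bindings, function(b) list(node = b$node, value = b$entry$struct)),
         struct = instantiate_pattern_sem(pattern$sem, vals))
  })
}

instantiate_pattern_sem <- function(sem, values) {
  if (is_sem_var(sem)) {
    v <- values[[sem$name]]
    if (is.null(v)) stop("unbound variable '", sem$name, "'", call. = FALSE)
    return(v)
  }
  if (is_sem_struct(sem)) {
    slots <- lapply(sem$slots, instantiate_pattern_sem, values = values)
    return(sem_struct(sem$concept, slots))
  }
  sem
}

## ---- bottom-up composition -------------------------------------------------

#' Compose explicit events from one sentence
#'
#' Traverses the dependency tree in post-order. Entity mentions seed atomic
#' semantics at their head tokens; at every node each pattern is matched with
#' [match_at()] semantics, and each match instantiates the pattern's semantic
#' structure with the semantics of the matched descendants, adding it to the
#' node's semantics. A node may accumulate several structures (all pattern
#' matches stack; coordinated conjuncts yield one structure per conjunct). A
#' structure consumed as a variable filler of a later match is not emitted
#' separately: the maximal (non-embedded) pattern-derived structures become
#' the sentence's explicit events.
#'
#' @param graph a `dep_graph`.
#' @param mentions mentions from [recognize()] for this sentence.
#' @param patterns list of `pattern_pair` objects.
#' @param ont a `gro_ontology`.
#' @param control a [match_control()].
#' @param doc document identifier for provenance.
#' @param details also return the per-node semantics index.
#' @return list of `gr_event` objects (or, with `details = TRUE`, a list with
#'   elements `events` and `semantics`).
#' @export
compose <- function(graph, mentions, patterns, ont, control = match_control(),
                    doc = "doc1", details = FALSE) {
  n <- nrow(graph$tokens)
  semx <- vector("list", n)
  consumed <- new.env(parent = emptyenv())
  uid <- 0L
  new_entry <- function(struct, sig, source, pattern = NA_character_, trigger = NA_integer_) {
    uid <<- uid + 1L
    list(struct = struct, sig = sig, uid = uid, source = source,
         pattern = pattern, trigger = trigger)
  }
  for (m in mentions) {
    e <- mention_entity(m)
    semx[[m$head]] <- c(semx[[m$head]], list(new_entry(e, m$id, "entity", trigger = m$head)))
  }
  depth_of <- vapply(seq_len(n), function(i) {
    d <- 0L; u <- i
    while (graph$tokens$head[u] != 0L) { d <- d + 1L; u <- graph$tokens$head[u] }
    d
  }, 0L)
  has_neg <- any(tolower(graph$tokens$lemma) %in% control$negation)
  for (node in order(depth_of, decreasing = TRUE)) {
    for (pat in patterns) {
      ms <- match_syn_at(pat$syn, node, graph, semx, ont, control)
      for (m in ms) {
        vals <- lapply(m$bindings, function(b) b$entry$struct)
        struct <- instantiate_pattern_sem(pat$sem, vals)
        attr(struct, "trigger") <- c(sentence = graph$sentence, node = node)
        for (b in m$bindings) assign(as.character(b$entry$uid), TRUE, envir = consumed)
        semx[[node]] <- c(semx[[node]], list(
          new_entry(struct, paste(sem_entity_ids(struct), collapse = ","),
                    "pattern", pattern = pat$id, trigger = node)))
      }
    }
  }
  events <- list()
  for (node in seq_len(n)) {
    for (entry in semx[[node]]) {
      if (entry$source != "pattern") next
      if (exists(as.character(entry$uid), envir = consumed)) next
      events[[length(events) + 1L]] <- gr_event(
        entry$struct, origin = "explicit", doc = doc,
        sentences = graph$sentence, source = entry$pattern,
        trigger = c(sentence = graph$sentence, node = node),
        negated = has_neg)
    }
  }
  if (!details) return(events)
  list(events = events,
       semantics = lapply(semx, function(es) lapply(es, `[[`, "struct")))
}

## ---- events ----------------------------------------------------------------

#' Construct an event
#'
#' An event is a fully instantiated (variable-free) semantic structure with
#' provenance: origin (`explicit` from pattern matching, `inferred` from rule
#' application), document, supporting sentence indices, the pattern or rule
#' id, and for inferred events the supporting events.
#'
#' @param struct a ground `sem_struct`.
#' @param origin `"explicit"` or `"inferred"`.
#' @param doc document identifier.
#' @param sentences integer vector of supporting sentence indices.
#' @param source pattern or rule identifier.
#' @param supports list of supporting `gr_event`s (inferred events only).
#' @param trigger named vector `(sentence, node)` of the head match.
#' @param negated whether a negation cue occurred in a supporting sentence
#'   (carried in provenance, not interpreted).
#' @return An object of class `gr_event`.
#' @export
gr_event <- function(struct, origin, doc, sentences, source,
                     supports = list(), trigger = NULL, negated = FALSE) {
  stopifnot(sem_is_ground(struct))
  structure(list(struct = struct, origin = origin, doc = doc,
                 sentences = sort(unique(as.integer(sentences))),
                 source = source, supports = supports, trigger = trigger,
                 negated = negated),
            class = "gr_event")
}

#' @export
print.gr_event <- function(x, ...) {
  cat("<gr_event ", x$origin, " ", x$source, " doc=", x$doc,
      " sent=", paste(x$sentences, collapse = ","), ">\n  ",
      canonical_form(x$struct), "\n", sep = "")
  invisible(x)
}
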