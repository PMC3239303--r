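# Shared builders and independent oracles for the test suite.

test_ontology <- local({
  ont <- NULL
  function() {
    if (is.null(ont)) ont <<- load_ontology()
    ont
  }
})

test_patterns <- local({
  pats <- NULL
  function() {
    if (is.null(pats)) pats <<- load_patterns(ont = test_ontology())
    pats
  }
})

test_rules <- local({
  rules <- NULL
  function() {
    if (is.null(rules)) rules <<- load_rules(ont = test_ontology())
    rules
  }
})

test_templates <- local({
  tpls <- NULL
  function() {
    if (is.null(tpls)) tpls <<- load_templates(ont = test_ontology())
    tpls
  }
})

write_dict <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

him_dictionary <- function() {
  load_dictionary(write_dict(rbind(make_dict_rows(tfs = c("himA", "himD")),
                                   make_dict_rows(genes = "fimA"))),
                  test_ontology())
}

## Compose the reconstructed cascade sentence "lesions in himA cause a
## reduction in expression of fimA" end to end; returns events + semantics.
cascade_example <- function(frame = "cascade") {
  ont <- test_ontology()
  g <- read_conllu(frame_sentence(frame, agent = "himA", agent2 = "himD",
                                  patient = "fimA"))[[1]]
  ms <- recognize(g, him_dictionary())
  c(list(graph = g, mentions = ms),
    compose(g, ms, test_patterns(), ont, details = TRUE))
}

## ---- independent oracles ---------------------------------------------------

## Brute-force reflexive-transitive closure over an edge list (child, parent).
oracle_reaches <- function(edges, a, b) {
  if (a == b) return(TRUE)
  frontier <- a
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

## Brute-force descendant set by iterating the child relation to fixpoint.
oracle_descendants <- function(heads, node) {
  out <- integer(0)
  frontier <- which(heads == node)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- which(heads %in% frontier)
  }
  sort(out)
}

## Random dependency tree as a dep_graph: parent of token i drawn from 1..i-1,
## guaranteeing a single root and no cycles.
random_tree <- function(n, lemmas, upos = NULL, deprels = NULL) {
  heads <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  if (is.null(upos)) upos <- sample(c("NOUN", "VERB", "ADP"), n, replace = TRUE)
  if (is.null(deprels)) {
    deprels <- c("root", sample(c("nsubj", "dobj", "pobj", "conj", "det"),
                                n - 1L, replace = TRUE))
  }
  lines <- sprintf("%d\t%s\t%s\t%s\t_\t_\t%d\t%s\t_\t_",
                   seq_len(n), lemmas, lemmas, upos, heads, deprels)
  read_conllu(c(lines, ""))[[1]]
}

## Independent enumeration of all (a, b) node assignments for a two-item
## pattern (Subject:A Object:B) at `head_node`, applying the three loose-match
## conditions directly on the tree.
oracle_two_item_assignments <- function(graph, head_node, boundary) {
  toks <- graph$tokens
  desc <- oracle_descendants(toks$head, head_node)
  path_nodes <- function(d) {
    p <- integer(0); u <- d
    while (u != head_node) { p <- c(u, p); u <- toks$head[u] }
    p
  }
  ok_path <- function(d) {
    between <- path_nodes(d)
    between <- between[-length(between)]
    marked <- unique(c(between, which(toks$head %in% between)))
    !any(tolower(toks$lemma[marked]) %in% boundary)
  }
  role_on_path <- function(d, wanted) {
    roles <- toks$role[path_nodes(d)]
    if (wanted == "Subject") any(roles == "Subject")
    else any(roles %in% c("Object", "PrepObject"))
  }
  subj <- Filter(function(d) ok_path(d) && role_on_path(d, "Subject"), desc)
  obj <- Filter(function(d) ok_path(d) && role_on_path(d, "Object"), desc)
  out <- list()
  for (a in subj) {
    for (b in obj) {
      if (a == b) next
      if (b %in% oracle_descendants(toks$head, a)) next
      if (a %in% oracle_descendants(toks$head, b)) next
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  out
}

## ---- independent forward-chaining oracle for the flattening rules ----------

RP_FAMILY <- c("RegulatoryProcess", "RegulationOfGeneExpression",
               "RegulationOfTranscription", "PositiveRegulation",
               "NegativeRegulation", "BindingOfTFToTFBindingSiteOfDNA")
GE_FAMILY <- c("GeneExpression", "Transcription")

oracle_serialize <- function(x) {
  if (inherits(x, "sem_entity")) return(paste0("E(", x$id, ")"))
  if (is.character(x)) return(paste0("L(", x, ")"))
  props <- sort(names(x$slots))
  paste0("S(", x$concept, ";",
         paste(vapply(props, function(p) paste0(p, ":", oracle_serialize(x$slots[[p]])), ""),
               collapse = ";"), ")")
}

oracle_nxor <- function(p1, p2) {
  if (p1 == "unknown" || p2 == "unknown") return("unknown")
  if (p1 == p2) "positive" else "negative"
}

oracle_pol <- function(s) {
  p <- s$slots$hasPolarity
  if (is.null(p)) "positive" else p
}

## One rule application sweep over a set of structures; mirrors the shipped
## flattening/specialization rules R1-R3 including slot carry-over.
oracle_apply_rules <- function(structs) {
  out <- list()
  for (s in structs) {
    if (!inherits(s, "sem_struct") || !s$concept %in% RP_FAMILY) next
    ag <- s$slots$hasAgent
    pt <- s$slots$hasPatient
    if (inherits(ag, "sem_struct") && ag$concept %in% RP_FAMILY &&
        !is.null(ag$slots$hasPatient)) {
      slots <- list(hasAgent = ag$slots$hasPatient,
                    hasPolarity = oracle_nxor(oracle_pol(ag), oracle_pol(s)))
      if (!is.null(pt)) slots$hasPatient <- pt
      out[[length(out) + 1L]] <- sem_struct("RegulatoryProcess", slots)
    }
    if (inherits(pt, "sem_struct") && pt$concept %in% RP_FAMILY &&
        !is.null(pt$slots$hasPatient)) {
      slots <- list(hasPatient = pt$slots$hasPatient,
                    hasPolarity = oracle_nxor(oracle_pol(pt), oracle_pol(s)))
      if (!is.null(ag)) slots$hasAgent <- ag
      out[[length(out) + 1L]] <- sem_struct("RegulatoryProcess", slots)
    }
    if (inherits(pt, "sem_struct") && pt$concept %in% GE_FAMILY) {
      slots <- list(hasPatient = pt)
      if (!is.null(ag)) slots$hasAgent <- ag
      if (!is.null(s$slots$hasPolarity)) slots$hasPolarity <- s$slots$hasPolarity
      out[[length(out) + 1L]] <- sem_struct("RegulationOfGeneExpression", slots)
    }
  }
  out
}

oracle_closure <- function(structs) {
  seen <- vapply(structs, oracle_serialize, "")
  all <- structs
  repeat {
    fresh <- oracle_apply_rules(all)
    keys <- vapply(fresh, oracle_serialize, "")
    new <- !keys %in% seen & !duplicated(keys)
    if (!any(new)) return(all)
    all <- c(all, fresh[new])
    seen <- c(seen, keys[new])
  }
}

## Random small regulation event for closure property tests.
random_event_struct <- function(entities = paste0("X", 1:4), depth = 2L) {
  ent <- function() sem_entity(sample(entities, 1L), "x", "Gene")
  pol <- function() sample(c("positive", "negative", NA), 1L)
  build <- function(d) {
    slots <- list()
    slots$hasPatient <- if (d > 0L && stats::runif(1) < 0.5) build(d - 1L)
      else if (stats::runif(1) < 0.3) sem_struct("GeneExpression", list(hasPatient = ent()))
      else ent()
    if (stats::runif(1) < 0.7) {
      slots$hasAgent <- if (d > 0L && stats::runif(1) < 0.3) build(d - 1L) else ent()
    }
    p <- pol()
    if (!is.na(p)) slots$hasPolarity <- p
    sem_struct("RegulatoryProcess", slots)
  }
  build(depth)
}

as_events <- function(structs, doc = "doc1") {
  lapply(structs, gr_event, origin = "explicit", doc = doc, sentences = 1L,
         source = "Pxx")
}

event_canon <- function(events) sort(vapply(events, function(e) canonical_form(e$struct), ""))
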