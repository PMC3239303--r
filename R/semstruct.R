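#' @title Semantic structures
#'
#' @description
#' A semantic structure is a concept-rooted attribute structure
#' `<Concept prop=value ...>` whose values are nested structures, grounded
#' entity references, string literals (e.g. `"negative"`, `"yes"`), variables,
#' or (in rule conclusions) function calls such as
#' `polarity_sum(Polarity1,Polarity2)`. The same representation serves as
#' semantic pattern, inference-rule condition/conclusion, extraction template
#' and (when variable-free) as event structure.
#'
#' @param concept GRO concept name.
#' @param slots named list of slot values (names are property names).
#' @return An object of class `sem_struct`.
#' @export
sem_struct <- function(concept, slots = list()) {
  stopifnot(is.character(concept), length(concept) == 1L)
  structure(list(concept = concept, slots = slots), class = "sem_struct")
}

#' Create an entity reference value
#'
#' Entity references are the leaves of ground event structures: a grounding
#' identifier, the surface string it matched, and the set of ontology concept
#' labels carried by the dictionary entry.
#'
#' @param id grounding identifier (e.g. a UniProt accession).
#' @param surface matched surface text.
#' @param labels character vector of concept labels.
#' @return An object of class `sem_entity`.
#' @export
sem_entity <- function(id, surface, labels) {
  structure(list(id = id, surface = surface, labels = labels),
            class = "sem_entity")
}

sem_var <- function(name, concept = NA_character_) {
  structure(list(name = name, concept = concept), class = "sem_var")
}

sem_call <- function(fn, args) {
  structure(list(fn = fn, args = args), class = "sem_call")
}

#' Type predicates for semantic values
#'
#' @param x any object.
#' @return logical scalar.
#' @export
is_sem_struct <- function(x) inherits(x, "sem_struct")

#' @rdname is_sem_struct
#' @export
is_sem_entity <- function(x) inherits(x, "sem_entity")
is_sem_var    <- function(x) inherits(x, "sem_var")
is_sem_call   <- function(x) inherits(x, "sem_call")
is_sem_literal <- function(x) is.character(x) && length(x) == 1L

## ---- DSL parser ------------------------------------------------------------

## Tokenizer shared by the semantic-structure DSL. Tokens: '<' '>' '=' '(' ')'
## ',' quoted strings, and bare identifiers (may contain '?', '_', alnum).
sem_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("<", ">", "=", "(", ")", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    if (ch == "\"" || ch == "“" || ch == "”") {
      j <- i + 1L
      while (j <= n && !substr(text, j, j) %in% c("\"", "“", "”")) {
        j <- j + 1L
      }
      if (j > n) stop("unterminated string literal at position ", i, call. = FALSE)
      tokens[[length(tokens) + 1L]] <-
        list(type = "string", value = substr(text, i + 1L, j - 1L), pos = i)
      i <- j + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[?A-Za-z0-9_.:-]+", substr(text, i, n)))
    if (length(m) == 0L) stop("unexpected character '", ch, "' at position ", i, call. = FALSE)
    tokens[[length(tokens) + 1L]] <- list(type = "ident", value = m, pos = i)
    i <- i + nchar(m)
  }
  tokens
}

## Recursive-descent parser over the token stream held in an environment.
sem_parse_struct <- function(st, ont, opts) {
  tok <- sem_peek(st)
  if (is.null(tok) || tok$type != "<") {
    stop("expected '<' at position ", if (is.null(tok)) "end" else tok$pos, call. = FALSE)
  }
  sem_next(st)
  ctok <- sem_next(st)
  if (is.null(ctok) || ctok$type != "ident") stop("expected concept name after '<'", call. = FALSE)
  concept <- ctok$value
  if (!is.null(ont)) concept <- resolve_concept(ont, concept)
  slots <- list()
  repeat {
    tok <- sem_peek(st)
    if (is.null(tok)) stop("unterminated structure: missing '>'", call. = FALSE)
    if (tok$type == ">") { sem_next(st); break }
    if (tok$type != "ident") stop("expected property name at position ", tok$pos, call. = FALSE)
    sem_next(st)
    prop <- tok$value
    if (!is.null(ont) && !prop %in% ont$properties) {
      stop("unknown property '", prop, "'", call. = FALSE)
    }
    eq <- sem_next(st)
    if (is.null(eq) || eq$type != "=") stop("expected '=' after property '", prop, "'", call. = FALSE)
    slots[[prop]] <- sem_parse_value(st, ont, opts)
  }
  sem_struct(concept, slots)
}

sem_parse_value <- function(st, ont, opts) {
  tok <- sem_peek(st)
  if (is.null(tok)) stop("unexpected end of input in value position", call. = FALSE)
  if (tok$type == "<") return(sem_parse_struct(st, ont, opts))
  if (tok$type == "string") { sem_next(st); return(tok$value) }
  if (tok$type != "ident") stop("unexpected token '", tok$value, "' at position ", tok$pos, call. = FALSE)
  sem_next(st)
  name <- tok$value
  nxt <- sem_peek(st)
  if (!is.null(nxt) && nxt$type == "(") {
    if (!isTRUE(opts$allow_calls)) stop("function call '", name, "' not allowed here", call. = FALSE)
    if (!name %in% c("polarity_sum")) stop("unknown function '", name, "'", call. = FALSE)
    sem_next(st)
    args <- character(0)
    repeat {
      a <- sem_next(st)
      if (is.null(a) || a$type != "ident") stop("expected variable in call to ", name, call. = FALSE)
      args <- c(args, a$value)
      sep <- sem_next(st)
      if (is.null(sep)) stop("unterminated call to ", name, call. = FALSE)
      if (sep$type == ")") break
      if (sep$type != ",") stop("expected ',' or ')' in call to ", name, call. = FALSE)
    }
    return(sem_call(name, args))
  }
  if (!isTRUE(opts$allow_vars)) stop("variable '", name, "' not allowed here", call. = FALSE)
  ## '?Concept' template variables; bare capitalized names are rule/pattern
  ## variables whose name doubles as a concept constraint when it is declared.
  if (startsWith(name, "?")) {
    cn <- substring(name, 2L)
    if (!is.null(ont)) cn <- resolve_concept(ont, cn)
    return(sem_var(cn, concept = cn))
  }
  constraint <- NA_character_
  if (!is.null(ont) && concept_declared(ont, name)) {
    constraint <- resolve_concept(ont, name)
    name <- constraint
  }
  sem_var(name, concept = constraint)
}

sem_peek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
sem_next <- function(st) { tok <- sem_peek(st); if (!is.null(tok)) st$i <- st$i + 1L; tok }

#' Parse a semantic-structure expression
#'
#' Parses the angle-bracket DSL, e.g.
#' `<RegulatoryProcess hasAgent=Agent hasPolarity="negative">`. Bare
#' capitalized identifiers are variables; a variable whose name is a declared
#' ontology concept (after alias resolution) is constrained to bind values of
#' that concept or a subconcept. `?Concept` variables (used in extraction
#' templates) are always concept-constrained.
#'
#' @param text a single DSL string.
#' @param ont an [Ontology][load_ontology] used to validate concepts and
#'   properties, or `NULL` to skip validation.
#' @param allow_vars allow variables in value positions.
#' @param allow_calls allow function-call values (rule conclusions only).
#' @return A `sem_struct`.
#' @export
parse_sem <- function(text, ont = NULL, allow_vars = TRUE, allow_calls = FALSE) {
  st <- new.env(parent = emptyenv())
  st$tokens <- sem_tokenize(text)
  st$i <- 1L
  out <- sem_parse_struct(st, ont, list(allow_vars = allow_vars, allow_calls = allow_calls))
  if (!is.null(sem_peek(st))) {
    stop("trailing input after structure: '", sem_peek(st)$value, "'", call. = FALSE)
  }
  out
}

## ---- canonical form, variables, utilities ----------------------------------

#' Canonical form of a semantic value
#'
#' Serializes a structure deterministically (slots sorted by property name,
#' entities by grounding identifier, provenance excluded) so that structurally
#' equal events have equal strings. Used for fixpoint deduplication and for
#' unique-event counting.
#'
#' @param x a `sem_struct`, `sem_entity`, literal, variable or call.
#' @return A single string.
#' @export
canonical_form <- function(x) {
  if (is_sem_entity(x)) return(paste0("@", x$id))
  if (is_sem_literal(x)) return(paste0("\"", x, "\""))
  if (is_sem_var(x)) return(paste0("?", x$name))
  if (is_sem_call(x)) return(paste0(x$fn, "(", paste(x$args, collapse = ","), ")"))
  if (is_sem_struct(x)) {
    props <- sort(names(x$slots))
    inner <- vapply(props, function(p) paste0(p, "=", canonical_form(x$slots[[p]])), "")
    return(paste0("<", x$concept,
                  if (length(inner)) paste0(" ", paste(inner, collapse = " ")) else "",
                  ">"))
  }
  stop("not a semantic value", call. = FALSE)
}

#' @export
format.sem_struct <- function(x, ...) canonical_form(x)

#' @export
print.sem_struct <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.sem_entity <- function(x, ...) paste0(x$surface, "[", x$id, "]")

#' @export
print.sem_entity <- function(x, ...) {
  cat(format(x), " {", paste(x$labels, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

## All variable names occurring in a pattern structure (incl. call arguments).
sem_vars <- function(x) {
  if (is_sem_var(x)) return(x$name)
  if (is_sem_call(x)) return(x$args)
  if (is_sem_struct(x)) return(unique(unlist(lapply(x$slots, sem_vars), use.names = FALSE)))
  character(0)
}

## Grounding identifiers of all entities contained in a value (the "mention
## signature" used to collapse equivalent loose-match alternatives).
sem_entity_ids <- function(x) {
  if (is_sem_entity(x)) return(x$id)
  if (is_sem_struct(x)) {
    return(sort(unique(unlist(lapply(x$slots, sem_entity_ids), use.names = FALSE))))
  }
  character(0)
}

sem_is_ground <- function(x) {
  if (is_sem_var(x) || is_sem_call(x)) return(FALSE)
  if (is_sem_struct(x)) return(all(vapply(x$slots, sem_is_ground, TRUE)))
  TRUE
}

## Count of concept-rooted nodes in a compositional structure ("basic event
## instances"): entities are participants, not events.
#' Count basic event instances in a compositional structure
#'
#' @param x a `sem_struct`.
#' @param concept optionally count only nodes of this exact concept.
#' @return integer count of concept-rooted nodes.
#' @export
basic_instances <- function(x, concept = NULL) {
  if (!is_sem_struct(x)) return(0L)
  self <- if (is.null(concept) || identical(x$concept, concept)) 1L else 0L
  self + sum(vapply(x$slots, basic_instances, 0L, concept = concept))
}
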