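#' Load a Gene Regulation Ontology file
#'
#' Reads the plain-text ontology DSL: one declaration per line, `concept X`,
#' `isa Child Parent`, `property p`, or `alias Short LongConceptName`; blank
#' lines and `#` comments are ignored. The is-a graph must be acyclic (multiple
#' parents are allowed), every edge endpoint must be a declared concept, and
#' every alias must resolve to a declared concept.
#'
#' @param path path to an ontology file; defaults to the miniature gene
#'   regulation ontology shipped with the package.
#' @return An object of class `gro_ontology` with elements `concepts`,
#'   `isa` (child/parent edge data frame), `properties`, `aliases`, and a
#'   precomputed ancestor table.
#' @examples
#' ont <- load_ontology()
#' is_subconcept(ont, "NegativeRegulation", "RegulatoryProcess")
#' @export
load_ontology <- function(path = system.file("extdata", "gro_core.txt",
                                             package = "regevents")) {
  lines <- readLines(path, warn = FALSE)
  concepts <- character(0)
  properties <- character(0)
  aliases <- list()
  edges <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    parts <- strsplit(raw, "[[:space:]]+")[[1]]
    kw <- parts[[1]]
    if (kw == "concept" && length(parts) == 2L) {
      concepts <- c(concepts, parts[[2]])
    } else if (kw == "isa" && length(parts) == 3L) {
      edges[[length(edges) + 1L]] <- parts[2:3]
    } else if (kw == "property" && length(parts) == 2L) {
      properties <- c(properties, parts[[2]])
    } else if (kw == "alias" && length(parts) == 3L) {
      aliases[[parts[[2]]]] <- parts[[3]]
    } else {
      stop("ontology parse error at line ", ln, ": '", lines[[ln]], "'", call. = FALSE)
    }
  }
  if (length(concepts) == 0L) stop("ontology declares no concepts", call. = FALSE)
  if (anyDuplicated(concepts)) {
    stop("duplicate concept declaration: ",
         paste(unique(concepts[duplicated(concepts)]), collapse = ", "), call. = FALSE)
  }
  isa <- if (length(edges)) {
    data.frame(child = vapply(edges, `[[`, "", 1L),
               parent = vapply(edges, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0))
  }
  bad <- setdiff(unique(c(isa$child, isa$parent)), concepts)
  if (length(bad)) {
    stop("isa edge references undeclared concept(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unlist(aliases, use.names = FALSE), concepts)
  if (length(bad)) {
    stop("alias target(s) not declared: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(concepts)
  if (nrow(isa)) {
    g <- igraph::add_edges(g, rbind(isa$child, isa$parent))
  }
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc)
    stop("is-a graph contains a cycle (e.g. involving ",
         paste(unique(as.vector(ends)), collapse = " <-> "), ")", call. = FALSE)
  }
  ## reflexive-transitive closure: ancestors (incl. self) per concept
  ancestors <- lapply(concepts, function(cn) {
    names(igraph::subcomponent(g, cn, mode = "out"))
  })
  names(ancestors) <- concepts
  structure(list(concepts = concepts, isa = isa, properties = properties,
                 aliases = aliases, ancestors = ancestors),
            class = "gro_ontology")
}

#' Resolve a concept name through the alias table
#'
#' Alias resolution is idempotent: the result is always a declared concept
#' name, never another alias.
#'
#' @param ont a `gro_ontology`.
#' @param name concept name or alias (e.g. `"TFBS"`).
#' @return The declared concept name.
#' @export
resolve_concept <- function(ont, name) {
  if (!is.null(ont$aliases[[name]])) name <- ont$aliases[[name]]
  if (!name %in% ont$concepts) stop("unknown concept '", name, "'", call. = FALSE)
  name
}

concept_declared <- function(ont, name) {
  name %in% ont$concepts || !is.null(ont$aliases[[name]])
}

#' Subsumption query
#'
#' `TRUE` iff concept `a` equals `b` or reaches `b` through is-a edges
#' (reflexive-transitive closure). Aliases are resolved first.
#'
#' @param ont a `gro_ontology`.
#' @param a,b concept names or aliases.
#' @return logical scalar.
#' @export
is_subconcept <- function(ont, a, b) {
  a <- resolve_concept(ont, a)
  b <- resolve_concept(ont, b)
  b %in% ont$ancestors[[a]]
}

## Does any of the concept labels of `x` (an entity, structure, or bare
## concept name) fall under concept `cn`? Entities succeed if ANY label does
## (gene/protein metonymy).
value_under_concept <- function(ont, x, cn) {
  if (is_sem_entity(x)) {
    return(any(vapply(x$labels, function(l) is_subconcept(ont, l, cn), TRUE)))
  }
  if (is_sem_struct(x)) return(is_subconcept(ont, x$concept, cn))
  if (is.character(x) && length(x) == 1L) return(is_subconcept(ont, x, cn))
  FALSE
}

#' @export
print.gro_ontology <- function(x, ...) {
  cat("<gro_ontology> ", length(x$concepts), " concepts, ",
      nrow(x$isa), " is-a edges, ", length(x$properties), " properties, ",
      length(x$aliases), " aliases\n", sep = "")
  invisible(x)
}
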