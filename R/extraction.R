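#' Load semantic event templates
#'
#' Tab-separated file: template id, template pattern, associated label (e.g. a
#' Gene Ontology concept string). Template variables are written `?Concept`
#' and bind grounded entity mentions whose concept label is identical to or a
#' subconcept of the named concept; non-variable parts are fixed restrictions
#' on the event structure.
#'
#' @param path template file; defaults to the database templates shipped with
#'   the package.
#' @param ont a `gro_ontology`.
#' @return list of `event_template` objects.
#' @export
load_templates <- function(path = system.file("extdata", "templates.tsv",
                                              package = "regevents"),
                           ont = load_ontology()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("template row ", i, " malformed", call. = FALSE)
    id <- trimws(f[[1]])
    pat <- parse_sem(trimws(f[[2]]), ont, allow_vars = TRUE)
    label <- if (length(f) >= 3L) trimws(f[[3]]) else NA_character_
    vars <- sem_vars(pat)
    if (length(vars) == 0L) stop("template ", id, " has no variables", call. = FALSE)
    roles <- template_var_roles(pat)
    structure(list(id = id, pattern = pat, label = label, vars = vars,
                   roles = roles),
              class = "event_template")
  })
}

## Participant role of each variable: the top-level slot under which it occurs
## (hasAgent -> agent, hasPatient -> patient, anything else -> slot name).
template_var_roles <- function(pat) {
  roles <- character(0)
  for (prop in names(pat$slots)) {
    vs <- sem_vars(pat$slots[[prop]])
    role <- switch(prop, hasAgent = "agent", hasPatient = "patient",
                   sub("^has", "", prop))
    roles[vs] <- tolower(role)
  }
  roles
}

#' @export
print.event_template <- function(x, ...) {
  cat("<event_template> ", x$id, ": ", canonical_form(x$pattern),
      if (!is.na(x$label)) paste0("  [", x$label, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Match an event against a semantic template
#'
#' The event's root concept must be identical to or a subconcept of the
#' template's root concept, all fixed slots must be present with recursively
#' matching values (extra event slots are permitted), and every `?Concept`
#' variable must bind a grounded entity whose label falls under the concept.
#'
#' @param template an `event_template`.
#' @param event a `gr_event` (variable-free).
#' @param ont a `gro_ontology`.
#' @return A one-row extraction record data frame, or `NULL` when the event
#'   does not fit the template.
#' @export
match_template <- function(template, event, ont) {
  bindings <- match_condition(template$pattern, event, list(), ont)
  bindings <- Filter(function(b) all(vapply(b, is_sem_entity, TRUE)), bindings)
  if (length(bindings) == 0L) return(NULL)
  struct <- event$struct
  pol <- struct$slots$hasPolarity
  contact <- struct$slots$hasPhysicalContact
  rows <- lapply(bindings, function(b) {
    agent_var <- names(which(template$roles == "agent"))
    patient_var <- names(which(template$roles == "patient"))
    agent <- if (length(agent_var)) b[[agent_var[[1]]]] else NULL
    patient <- if (length(patient_var)) b[[patient_var[[1]]]] else NULL
    data.frame(
      doc = event$doc, template = template$id,
      type = template$pattern$concept,
      agent_id = if (is.null(agent)) NA_character_ else agent$id,
      agent_surface = if (is.null(agent)) NA_character_ else agent$surface,
      patient_id = if (is.null(patient)) NA_character_ else patient$id,
      patient_surface = if (is.null(patient)) NA_character_ else patient$surface,
      polarity = if (is_sem_literal(pol)) pol else "unknown",
      physical_contact = if (is_sem_literal(contact)) contact else "no",
      origin = event$origin,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

empty_records <- function() {
  data.frame(doc = character(0), template = character(0), type = character(0),
             agent_id = character(0), agent_surface = character(0),
             patient_id = character(0), patient_surface = character(0),
             polarity = character(0), physical_contact = character(0),
             origin = character(0), event = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract database records from events
#'
#' Both explicit and inferred events may fit the templates. Records are
#' deduplicated on (document, template, participant bindings, polarity,
#' physical contact); when an explicit and an inferred event yield the same
#' record the explicit origin is kept.
#'
#' @param events list of `gr_event`s.
#' @param templates list of `event_template`s.
#' @param ont a `gro_ontology`.
#' @return extraction-record data frame with one row per unique record and an
#'   `event` column indexing the supporting event in `events`.
#' @export
extract_records <- function(events, templates, ont) {
  out <- list()
  for (i in seq_along(events)) {
    for (tpl in templates) {
      rec <- match_template(tpl, events[[i]], ont)
      if (is.null(rec)) next
      rec$event <- i
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0L) return(empty_records())
  recs <- do.call(rbind, out)
  key <- with(recs, paste(doc, template, agent_id, patient_id, polarity,
                          physical_contact, sep = "\r"))
  recs <- recs[order(key, recs$origin != "explicit"), , drop = FALSE]
  recs <- recs[!duplicated(with(recs, paste(doc, template, agent_id, patient_id,
                                            polarity, physical_contact,
                                            sep = "\r"))), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Score predicted records against gold records
#'
#' An extracted record is correct when a gold record of the same document has
#' the same agent and patient grounding identifiers and an event type that the
#' prediction's type matches up to subsumption (a more specific predicted type
#' satisfies a more general gold type). Polarity and physical contact are not
#' part of the correctness criterion. In `unique` mode both sides are first
#' collapsed to unique (document, type, agent, patient) combinations, the
#' protocol used for counting unique database events.
#'
#' @param predicted,gold data frames with columns `doc`, `type`, `agent_id`,
#'   `patient_id`.
#' @param ont a `gro_ontology`.
#' @param mode `"instance"` or `"unique"`.
#' @return An `event_metrics` object: tp, fp, fn, precision, recall, f.
#' @export
evaluate_records <- function(predicted, gold, ont,
                             mode = c("instance", "unique")) {
  mode <- match.arg(mode)
  cols <- c("doc", "type", "agent_id", "patient_id")
  p <- as.data.frame(predicted)[, cols, drop = FALSE]
  g <- as.data.frame(gold)[, cols, drop = FALSE]
  if (mode == "unique") {
    p <- unique(p); g <- unique(g)
  }
  hit <- function(row, pool) {
    any(pool$doc == row$doc &
          pool$agent_id == row$agent_id &
          pool$patient_id == row$patient_id &
          vapply(pool$type, function(ty) is_subconcept(ont, row$type, ty), TRUE))
  }
  tp <- 0L
  for (i in seq_len(nrow(p))) if (hit(p[i, ], g)) tp <- tp + 1L
  fn <- 0L
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    covered <- any(p$doc == row$doc &
                     p$agent_id == row$agent_id &
                     p$patient_id == row$patient_id &
                     vapply(p$type, function(ty) is_subconcept(ont, ty, row$type), TRUE))
    if (!covered) fn <- fn + 1L
  }
  metrics(tp = tp, fp = nrow(p) - tp, fn = fn)
}

#' Build a metrics object from raw counts
#'
#' Precision is TP/(TP+FP), recall TP/(TP+FN) (0 when undefined), F the
#' harmonic mean.
#'
#' @param tp,fp,fn non-negative counts.
#' @return An `event_metrics` object.
#' @export
metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f = f),
            class = "event_metrics")
}

#' @export
print.event_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  |  precision %.1f%%  recall %.1f%%  F %.2f\n",
              x$tp, x$fp, x$fn, 100 * x$precision, 100 * x$recall, x$f))
  invisible(x)
}

## ---- output writers --------------------------------------------------------

serialize_sem <- function(x) {
  if (is_sem_entity(x)) {
    return(list(kind = "entity", id = x$id, surface = x$surface,
                labels = as.list(x$labels)))
  }
  if (is_sem_literal(x)) return(list(kind = "literal", value = x))
  if (is_sem_struct(x)) {
    return(list(kind = "struct", concept = x$concept,
                slots = lapply(x$slots, serialize_sem)))
  }
  stop("cannot serialize non-ground value", call. = FALSE)
}

deserialize_sem <- function(x) {
  switch(x$kind,
         entity = sem_entity(x$id, x$surface, unlist(x$labels, use.names = FALSE)),
         literal = x$value,
         struct = sem_struct(x$concept, lapply(x$slots, deserialize_sem)),
         stop("unknown kind '", x$kind, "'", call. = FALSE))
}

#' Write events to JSON
#'
#' Full nested structures with provenance; supporting events are referenced by
#' index into the same file.
#'
#' @param events list of `gr_event`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  keys <- vapply(events, function(e) canonical_form(e$struct), "")
  payload <- lapply(events, function(e) {
    list(origin = e$origin, doc = e$doc, sentences = as.list(e$sentences),
         source = e$source, negated = e$negated,
         supports = as.list(match(vapply(e$supports, function(s) canonical_form(s$struct), ""),
                                  keys)),
         struct = serialize_sem(e$struct))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read events back from JSON
#'
#' @param path file written by [write_events_json()].
#' @return list of `gr_event`s (supports resolved by index).
#' @export
read_events_json <- function(path) {
  payload <- jsonlite::read_json(path)
  events <- lapply(payload, function(p) {
    gr_event(deserialize_sem(p$struct), origin = p$origin, doc = p$doc,
             sentences = unlist(p$sentences, use.names = FALSE),
             source = p$source, negated = isTRUE(p$negated))
  })
  for (i in seq_along(payload)) {
    idx <- unlist(payload[[i]]$supports, use.names = FALSE)
    idx <- idx[!is.na(idx)]
    events[[i]]$supports <- events[idx]
  }
  events
}

#' Write BioNLP-style standoff annotation
#'
#' Per document, a `.a1` file with entity T-lines (character offsets, 0-based,
#' half-open) and a `.a2` file with event-trigger T-lines, E-lines whose
#' arguments reference T ids (entities) or E ids (embedded events), and
#' A-lines for Polarity and PhysicalContact. Inferred events re-use the
#' trigger of their first supporting explicit event.
#'
#' @param events list of `gr_event`s.
#' @param mentions list of `entity_mention`s.
#' @param dir output directory.
#' @param graphs optional named list (per doc) of `dep_graph` lists, used to
#'   resolve trigger-token offsets; without it the first embedded mention
#'   anchors the trigger.
#' @return character vector of written paths, invisibly.
#' @export
write_standoff <- function(events, mentions, dir, graphs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  docs <- unique(c(vapply(events, `[[`, "", "doc"),
                   vapply(mentions, `[[`, "", "doc")))
  paths <- character(0)
  for (doc in docs) {
    dm <- Filter(function(m) m$doc == doc, mentions)
    de <- Filter(function(e) e$doc == doc, events)
    tlines <- character(0)
    tmap <- list()  # mention key -> T id
    tn <- 0L
    for (m in dm) {
      tn <- tn + 1L
      tid <- paste0("T", tn)
      tmap[[paste(m$id, m$char_start)]] <- tid
      tlines <- c(tlines, sprintf("%s\t%s %d %d\t%s",
                                  tid, m$labels[[1]], m$char_start, m$char_end,
                                  m$surface))
    }
    a1 <- file.path(dir, paste0(doc, ".a1"))
    writeLines(tlines, a1)
    st <- new.env(parent = emptyenv())
    st$tn <- tn; st$en <- 0L; st$an <- 0L
    st$lines <- character(0)
    st$emap <- list()
    dgs <- if (!is.null(graphs)) graphs[[doc]] else NULL
    for (e in de) emit_event_lines(e$struct, e, st, tmap, dgs)
    a2 <- file.path(dir, paste0(doc, ".a2"))
    writeLines(st$lines, a2)
    paths <- c(paths, a1, a2)
  }
  invisible(paths)
}

trigger_offsets <- function(struct, event, graphs) {
  tr <- attr(struct, "trigger")
  if (!is.null(tr) && !is.null(graphs)) {
    g <- graphs[[tr[["sentence"]]]]
    tok <- g$tokens[tr[["node"]], ]
    return(list(start = tok$start, end = tok$end, text = tok$form))
  }
  ## fall back: first embedded mention, walking provenance for inferred events
  first_mention <- function(x) {
    if (is_sem_entity(x)) return(attr(x, "mention"))
    if (is_sem_struct(x)) {
      for (s in x$slots) {
        m <- first_mention(s)
        if (!is.null(m)) return(m)
      }
    }
    NULL
  }
  m <- first_mention(struct)
  if (is.null(m) && length(event$supports)) m <- first_mention(event$supports[[1]]$struct)
  if (is.null(m)) return(list(start = 0L, end = 0L, text = ""))
  list(start = m$char_start, end = m$char_end, text = m$surface)
}

emit_event_lines <- function(struct, event, st, tmap, graphs) {
  key <- canonical_form(struct)
  if (!is.null(st$emap[[key]])) return(st$emap[[key]])
  args <- character(0)
  attrs <- list()
  for (prop in names(struct$slots)) {
    val <- struct$slots[[prop]]
    arg <- sub("^has", "", prop)
    if (is_sem_entity(val)) {
      m <- attr(val, "mention")
      tid <- if (!is.null(m)) tmap[[paste(m$id, m$char_start)]] else NULL
      if (is.null(tid)) {
        k <- which_id_key(tmap, val$id)
        if (!is.na(k)) tid <- tmap[[k]]
      }
      if (!is.null(tid)) args <- c(args, paste0(arg, ":", tid))
    } else if (is_sem_struct(val)) {
      sub_id <- emit_event_lines(val, event, st, tmap, graphs)
      args <- c(args, paste0(arg, ":", sub_id))
    } else {
      attrs[[arg]] <- val
    }
  }
  off <- trigger_offsets(struct, event, graphs)
  st$tn <- st$tn + 1L
  trig <- paste0("T", st$tn)
  st$lines <- c(st$lines, sprintf("%s\t%s %d %d\t%s", trig, struct$concept,
                                  off$start, off$end, off$text))
  st$en <- st$en + 1L
  eid <- paste0("E", st$en)
  st$lines <- c(st$lines,
                sprintf("%s\t%s:%s%s", eid, struct$concept, trig,
                        if (length(args)) paste0(" ", paste(args, collapse = " ")) else ""))
  for (a in names(attrs)) {
    st$an <- st$an + 1L
    st$lines <- c(st$lines, sprintf("A%d\t%s %s %s", st$an, a, eid, attrs[[a]]))
  }
  st$emap[[key]] <- eid
  eid
}

which_id_key <- function(tmap, id) {
  keys <- names(tmap)
  hit <- keys[startsWith(keys, paste0(id, " "))]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Write an edge table
#'
#' One row per record: document, agent id, patient id, event type, polarity,
#' physical contact — the shape used for database (regulatory-network)
#' comparison.
#'
#' @param records extraction-record data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_edges <- function(records, path) {
  cols <- c("doc", "agent_id", "patient_id", "type", "polarity", "physical_contact")
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all output formats for a pipeline result
#'
#' @param records extraction-record data frame.
#' @param events list of `gr_event`s.
#' @param mentions list of `entity_mention`s.
#' @param dir output directory.
#' @param formats subset of `c("json", "standoff", "edges")`.
#' @param graphs optional per-document graphs for trigger offsets.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(records, events, mentions, dir,
                          formats = c("json", "standoff", "edges"),
                          graphs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("json" %in% formats) {
    paths <- c(paths, write_events_json(events, file.path(dir, "events.json")))
  }
  if ("standoff" %in% formats) {
    paths <- c(paths, write_standoff(events, mentions, dir, graphs))
  }
  if ("edges" %in% formats) {
    paths <- c(paths, write_edges(records, file.path(dir, "edges.tsv")))
  }
  invisible(paths)
}

#' Read a flat key=value configuration file
#'
#' Values containing commas are split into character vectors; `#` comments and
#' blank lines are ignored.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'", call. = FALSE)
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1]])
    out[[trimws(kv[[1]])]] <- val
  }
  out
}
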