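#' Compose two regulation polarities
#'
#' Nested regulation polarities compose as NXOR over
#' \{positive = TRUE, negative = FALSE\}: two negatives make a positive,
#' `positive` is the identity. `unknown` absorbs: the result is `unknown`
#' whenever either input is.
#'
#' @param p1,p2 `"positive"`, `"negative"` or `"unknown"`.
#' @return A polarity value.
#' @examples
#' polarity_sum("negative", "negative")  # "positive"
#' @export
polarity_sum <- function(p1, p2) {
  ok <- c("positive", "negative", "unknown")
  if (!p1 %in% ok || !p2 %in% ok) {
    stop("polarity must be one of ", paste(ok, collapse = ", "), call. = FALSE)
  }
  if (p1 == "unknown" || p2 == "unknown") return("unknown")
  if (p1 == p2) "positive" else "negative"
}

#' Parse an inference rule
#'
#' Rule DSL: `RULEID: <Cond1> + <Cond2> => <Conclusion>`. Conditions and the
#' conclusion use the angle-bracket structure syntax; variables shared across
#' conditions unify; conclusion value positions may call
#' `polarity_sum(Var1,Var2)`. Every conclusion variable must occur in some
#' condition.
#'
#' @param text one rule line.
#' @param ont a `gro_ontology`.
#' @param id identifier used when the line carries no `RULEID:` prefix.
#' @return An object of class `inference_rule`.
#' @export
parse_rule <- function(text, ont, id = "R1") {
  text <- trimws(text)
  lt <- regexpr("<", text, fixed = TRUE)
  colon <- regexpr(":", text, fixed = TRUE)
  if (colon > 0 && (lt < 0 || colon < lt)) {
    id <- trimws(substr(text, 1L, colon - 1L))
    text <- trimws(substr(text, colon + 1L, nchar(text)))
  }
  halves <- strsplit(text, "=>", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("rule ", id, ": expected one '=>'", call. = FALSE)
  cond_texts <- split_top_level(trimws(halves[[1]]), "+")
  conditions <- lapply(cond_texts, parse_sem, ont = ont,
                       allow_vars = TRUE, allow_calls = FALSE)
  conclusion <- parse_sem(trimws(halves[[2]]), ont,
                          allow_vars = TRUE, allow_calls = TRUE)
  cvars <- unique(unlist(lapply(conditions, sem_vars), use.names = FALSE))
  unbound <- setdiff(sem_vars(conclusion), cvars)
  if (length(unbound)) {
    stop("rule ", id, ": conclusion variable(s) not bound by any condition: ",
         paste(unbound, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, conditions = conditions, conclusion = conclusion),
            class = "inference_rule")
}

## Split on a separator character occurring outside <...> nesting.
split_top_level <- function(text, sep) {
  depth <- 0L
  cuts <- integer(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[[i]] == "<") depth <- depth + 1L
    else if (chars[[i]] == ">") depth <- depth - 1L
    else if (chars[[i]] == sep && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    trimws(paste(chars[starts[[k]]:ends[[k]]], collapse = ""))
  }, "")
}

#' Load an inference-rule file
#'
#' @param path rule file (one rule per line, `#` comments allowed); defaults
#'   to the four rules shipped with the package.
#' @param ont a `gro_ontology`.
#' @return list of `inference_rule` objects.
#' @export
load_rules <- function(path = system.file("extdata", "rules.txt",
                                          package = "regevents"),
                       ont = load_ontology()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(seq_along(lines), function(i) {
    parse_rule(lines[[i]], ont, id = sprintf("R%d", i))
  })
}

#' @export
print.inference_rule <- function(x, ...) {
  cat("<inference_rule> ", x$id, ": ",
      paste(vapply(x$conditions, canonical_form, ""), collapse = " + "),
      " => ", canonical_form(x$conclusion), "\n", sep = "")
  invisible(x)
}

#' Match a rule condition against an event
#'
#' One-way unification of a condition pattern against a ground event
#' structure: the event concept must be identical to or a subconcept of the
#' condition concept, every condition slot must be present in the event with a
#' recursively matching value (extra event slots are permitted), and variables
#' bind consistently with the partial binding. A `hasPolarity=Var` slot
#' matches an event lacking polarity by binding the default `"positive"`
#' (the NXOR identity), so polarity-less events compose inertly.
#'
#' @param cond condition `sem_struct` (variables allowed).
#' @param event a `gr_event` or ground `sem_struct`.
#' @param binding named list of already-bound variables.
#' @param ont a `gro_ontology`.
#' @return list of extended bindings (empty if no match).
#' @export
match_condition <- function(cond, event, binding = list(), ont) {
  struct <- if (inherits(event, "gr_event")) event$struct else event
  match_value(cond, struct, binding, ont, top = TRUE)
}

match_value <- function(pat, val, binding, ont, top = FALSE) {
  if (is_sem_var(pat)) {
    if (!is.na(pat$concept) && !value_under_concept(ont, val, pat$concept)) {
      return(list())
    }
    prev <- binding[[pat$name]]
    if (!is.null(prev)) {
      if (identical(canonical_form(prev), canonical_form(val))) return(list(binding))
      return(list())
    }
    binding[[pat$name]] <- val
    return(list(binding))
  }
  if (is_sem_literal(pat)) {
    if (is_sem_literal(val) && pat == val) return(list(binding))
    return(list())
  }
  if (is_sem_struct(pat)) {
    if (!is_sem_struct(val)) return(list())
    if (!is_subconcept(ont, val$concept, pat$concept)) return(list())
    states <- list(binding)
    for (prop in names(pat$slots)) {
      pv <- pat$slots[[prop]]
      if (!prop %in% names(val$slots)) {
        ## missing-polarity default: hasPolarity=Var binds "positive"
        if (prop == "hasPolarity" && is_sem_var(pv)) {
          states <- unlist(lapply(states, function(b) {
            match_value(pv, "positive", b, ont)
          }), recursive = FALSE)
          if (length(states) == 0L) return(list())
          next
        }
        return(list())
      }
      vv <- val$slots[[prop]]
      states <- unlist(lapply(states, function(b) match_value(pv, vv, b, ont)),
                       recursive = FALSE)
      if (length(states) == 0L) return(list())
    }
    return(states)
  }
  stop("invalid condition value", call. = FALSE)
}

## Instantiate a conclusion pattern under a binding; polarity_sum calls are
## evaluated on the bound literals.
instantiate_conclusion <- function(pat, binding) {
  if (is_sem_var(pat)) {
    v <- binding[[pat$name]]
    if (is.null(v)) stop("unbound conclusion variable '", pat$name, "'", call. = FALSE)
    return(v)
  }
  if (is_sem_call(pat)) {
    args <- lapply(pat$args, function(a) {
      v <- binding[[a]]
      if (is.null(v)) stop("unbound call argument '", a, "'", call. = FALSE)
      if (!is_sem_literal(v)) return("unknown")
      v
    })
    return(do.call(polarity_sum, args))
  }
  if (is_sem_struct(pat)) {
    return(sem_struct(pat$concept, lapply(pat$slots, instantiate_conclusion,
                                          binding = binding)))
  }
  pat
}

#' Forward-chaining closure of a document's events
#'
#' Repeatedly applies every rule to the current event set (modus ponens: when
#' all conditions of a rule match events under a consistent binding, the
#' instantiated conclusion is added) until a pass generates no event that is
#' new under canonical-form deduplication. Conditions may be satisfied by
#' events from different sentences of the document, which is how
#' cross-sentence evidence is combined. Top-level slots of the first
#' condition's matched event that the condition does not mention and the
#' conclusion does not set are carried into the conclusion, so flattening
#' rules preserve the participants they do not rearrange.
#'
#' @param events list of `gr_event`s from one document.
#' @param rules list of `inference_rule`s.
#' @param ont a `gro_ontology`.
#' @param max_passes iteration cap guarding user-supplied rule sets that keep
#'   generating novel structures.
#' @return list of `gr_event`s: the input events followed by the inferred
#'   events, each inferred event carrying its rule id and supporting events.
#' @export
closure <- function(events, rules, ont, max_passes = 100L) {
  all_events <- events
  seen <- new.env(parent = emptyenv())
  for (ev in events) assign(canonical_form(ev$struct), TRUE, envir = seen)
  for (pass in seq_len(max_passes)) {
    added <- list()
    for (rule in rules) {
      states <- list(list(binding = list(), supports = list()))
      for (cond in rule$conditions) {
        nxt <- list()
        for (st in states) {
          for (ev in all_events) {
            exts <- match_condition(cond, ev, st$binding, ont)
            for (b in exts) {
              nxt[[length(nxt) + 1L]] <- list(binding = b,
                                              supports = c(st$supports, list(ev)))
            }
          }
        }
        states <- nxt
        if (length(states) == 0L) break
      }
      for (st in states) {
        concl <- instantiate_conclusion(rule$conclusion, st$binding)
        concl <- carry_over_slots(concl, rule$conditions[[1]], st$supports[[1]]$struct)
        key <- canonical_form(concl)
        if (exists(key, envir = seen)) next
        assign(key, TRUE, envir = seen)
        added[[length(added) + 1L]] <- gr_event(
          concl, origin = "inferred",
          doc = st$supports[[1]]$doc,
          sentences = unlist(lapply(st$supports, `[[`, "sentences")),
          source = rule$id, supports = st$supports,
          negated = any(vapply(st$supports, `[[`, TRUE, "negated")))
      }
    }
    if (length(added) == 0L) return(all_events)
    all_events <- c(all_events, added)
  }
  stop("closure did not reach a fixpoint within ", max_passes,
       " passes; the rule set appears to generate unbounded novel structures",
       call. = FALSE)
}

## Copy top-level slots of the matched event that the (first) condition does
## not mention and the conclusion does not set.
carry_over_slots <- function(concl, cond, matched) {
  if (!is_sem_struct(concl) || !is_sem_struct(matched)) return(concl)
  extra <- setdiff(names(matched$slots),
                   union(names(cond$slots), names(concl$slots)))
  for (prop in extra) concl$slots[[prop]] <- matched$slots[[prop]]
  concl
}
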