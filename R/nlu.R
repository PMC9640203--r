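#' Define an intent
#'
#' An intent is a named conversational meaning (e.g. `sadness`, `fear`)
#' recognized from free text by case- and punctuation-insensitive phrase
#' patterns. Priority intents are additionally recognized *anywhere* in the
#' dialog, triggering a digression to a bound target node even when the
#' current node has no matching local edge.
#'
#' @param intent_id intent identifier (slug).
#' @param patterns non-empty character vector of keyword/phrase patterns.
#' @param is_priority is this a priority intent?
#' @param priority_target node id the dialog digresses to (required iff
#'   `is_priority`).
#' @return an `intent` object.
#' @export
intent <- function(intent_id, patterns, is_priority = FALSE,
                   priority_target = NULL) {
  stopifnot(is_scalar_character(intent_id), is.character(patterns),
            length(patterns) >= 1)
  if (isTRUE(is_priority) && is.null(priority_target))
    stop_cf("priority intent '%s' needs a priority_target", intent_id)
  patterns <- as.character(patterns)
  norm <- normalize_text(patterns) # matched pre-normalized, once
  structure(list(intent_id = intent_id, patterns = patterns,
                 patterns_norm = norm,
                 pattern_ntok = lengths(strsplit(norm, " ", fixed = TRUE)),
                 is_priority = isTRUE(is_priority),
                 priority_target = priority_target),
            class = "intent")
}

#' Build an intent registry
#'
#' @param intents list of [intent()] objects; ids must be unique.
#' @param fallback_id reserved identifier returned when nothing matches;
#'   must not collide with a real intent id.
#' @return an `intent_registry`.
#' @export
intent_registry <- function(intents, fallback_id = "fallback") {
  ids <- vapply(intents, `[[`, "", "intent_id")
  if (anyDuplicated(ids))
    stop_cf("duplicate intent id: %s", ids[duplicated(ids)][1])
  if (fallback_id %in% ids)
    stop_cf("fallback_id '%s' collides with a registered intent", fallback_id)
  names(intents) <- ids
  structure(list(intents = intents, fallback_id = fallback_id),
            class = "intent_registry")
}

#' @export
print.intent_registry <- function(x, ...) {
  np <- sum(vapply(x$intents, `[[`, TRUE, "is_priority"))
  cat(sprintf("<intent_registry> %d intents (%d priority), fallback '%s'\n",
              length(x$intents), np, x$fallback_id))
  invisible(x)
}

#' @export
length.intent_registry <- function(x) length(x$intents)

#' Build a risk lexicon
#'
#' Phrases whose appearance in user input, at any point in the dialog,
#' demands an immediate safety response: `self_harm` phrases trigger the
#' escalation protocol, `abuse` phrases digress to supportive content.
#'
#' @param self_harm character vector of self-harm phrase patterns.
#' @param abuse character vector of abuse-risk phrase patterns.
#' @return a `risk_lexicon`.
#' @export
risk_lexicon <- function(self_harm, abuse = character(0)) {
  stopifnot(length(self_harm) >= 1)
  structure(list(self_harm = as.character(self_harm),
                 abuse = as.character(abuse),
                 self_harm_norm = normalize_text(as.character(self_harm)),
                 abuse_norm = normalize_text(as.character(abuse))),
            class = "risk_lexicon")
}

# does `pattern` occur in `text` on word boundaries, after normalization?
# normalization leaves only alphanumerics and single spaces, so padding both
# sides with spaces makes a fixed substring search word-boundary-exact
phrase_hit <- function(text_norm, pattern) {
  p <- normalize_text(pattern)
  if (!nzchar(p)) return(FALSE)
  grepl(paste0(" ", p, " "), paste0(" ", text_norm, " "), fixed = TRUE)
}

# same, for an already-normalized pattern
phrase_hit_norm <- function(text_padded, pattern_norm)
  nzchar(pattern_norm) &&
    grepl(paste0(" ", pattern_norm, " "), text_padded, fixed = TRUE)

#' Classify free text to one intent
#'
#' A deterministic, dependency-free keyword classifier standing behind a
#' pluggable interface (any scorer with this signature can replace it).
#' Each intent is scored by its best-matching pattern: the score is the
#' matched pattern's token count divided by the input's token count
#' (capped at 1), so longer, more specific matches on shorter inputs score
#' higher. No match at all yields the registry's fallback id with score 0.
#' Ties break lexicographically on intent id, which keeps classification
#' reproducible.
#'
#' @param text user utterance.
#' @param registry an [intent_registry()].
#' @return an `intent_classification`: list with `intent_id`, `score`
#'   (in \[0,1\], 0 iff fallback) and `matched_pattern`.
#' @export
classify_text <- function(text, registry) {
  norm <- normalize_text(text %||% "")
  ntok <- length(tokenize(norm))
  best <- list(intent_id = registry$fallback_id, score = 0,
               matched_pattern = NULL)
  if (ntok == 0L)
    return(structure(best, class = "intent_classification"))
  padded <- paste0(" ", norm, " ")
  ids <- sort(names(registry$intents), method = "radix")
  for (id in ids) {
    it <- registry$intents[[id]]
    for (j in seq_along(it$patterns)) {
      if (!phrase_hit_norm(padded, it$patterns_norm[j])) next
      score <- min(1, it$pattern_ntok[j] / ntok)
      if (score > best$score) # strict: ties keep the lexicographically first
        best <- list(intent_id = id, score = score,
                     matched_pattern = it$patterns[j])
    }
  }
  structure(best, class = "intent_classification")
}

#' Scan text for risk phrases
#'
#' Case- and punctuation-insensitive; checked before any intent routing.
#' Self-harm takes precedence over abuse when both categories match.
#'
#' @param text user utterance.
#' @param lexicon a [risk_lexicon()].
#' @return `"self_harm"`, `"abuse"`, or `NULL` when nothing matches.
#' @export
match_risk <- function(text, lexicon) {
  norm <- normalize_text(text %||% "")
  if (!nzchar(norm)) return(NULL)
  padded <- paste0(" ", norm, " ")
  for (cat in c("self_harm", "abuse"))
    for (p in lexicon[[paste0(cat, "_norm")]] %||% normalize_text(lexicon[[cat]]))
      if (phrase_hit_norm(padded, p)) return(cat)
  NULL
}

#' Resolve routing for typed text at an input node
#'
#' Applies the strict precedence order that makes the agent responsive to
#' the user's agenda while keeping safety first:
#'
#' 1. risk phrase -> `risk_escalation` (self-harm; abuse-category risk is
#'    instead routed as the `abuse_risk` priority digression);
#' 2. classified intent has a local intent edge at this node -> `local_edge`;
#' 3. classified intent is a priority intent -> `priority_digression` to
#'    its bound target;
#' 4. otherwise -> the node's `fallback` edge.
#'
#' The function is total: every input string yields a decision.
#'
#' @param node the current `free_text` (or `quick_replies`) node.
#' @param text the typed input.
#' @param registry an [intent_registry()].
#' @param lexicon a [risk_lexicon()].
#' @param graph the dialog graph (for priority binding lookup).
#' @return a `routing_decision`: list with `kind` (one of
#'   `risk_escalation`, `local_edge`, `priority_digression`, `fallback`),
#'   `target` (node id, or `NA` for escalation), `intent_id` and `score`.
#' @export
resolve_routing <- function(node, text, registry, lexicon, graph) {
  decision <- function(kind, target, intent_id, score = NA_real_)
    structure(list(kind = kind, target = target, intent_id = intent_id,
                   score = score), class = "routing_decision")

  risk <- match_risk(text, lexicon)
  if (identical(risk, "self_harm"))
    return(decision("risk_escalation", NA_character_, "self_harm"))

  cls <- if (identical(risk, "abuse")) {
    list(intent_id = "abuse_risk", score = 1, matched_pattern = NULL)
  } else classify_text(text, registry)

  if (node$type == "free_text") {
    labels <- vapply(node$out_edges, `[[`, "", "label")
    hit <- which(labels == cls$intent_id & labels != "fallback")
    if (length(hit))
      return(decision("local_edge", node$out_edges[[hit[1]]]$target,
                      cls$intent_id, cls$score))
  }

  it <- registry$intents[[cls$intent_id]]
  if (!is.null(it) && it$is_priority) {
    target <- graph$priority_bindings[[cls$intent_id]] %||% it$priority_target
    if (!is.null(target))
      return(decision("priority_digression", target, cls$intent_id, cls$score))
  }
  if (identical(risk, "abuse")) {
    target <- graph$priority_bindings[["abuse_risk"]]
    if (!is.null(target))
      return(decision("priority_digression", target, "abuse_risk", 1))
  }

  if (node$type == "free_text") {
    labels <- vapply(node$out_edges, `[[`, "", "label")
    fb <- which(labels == "fallback")
    if (length(fb))
      return(decision("fallback", node$out_edges[[fb[1]]]$target,
                      registry$fallback_id, 0))
  }
  # typed text at a quick-replies node with nothing better: re-prompt
  decision("fallback", NA_character_, registry$fallback_id, 0)
}

# ---- YAML i/o --------------------------------------------------------------

#' Read an intent registry from YAML
#'
#' Format: a mapping with `fallback_id` and `intents`, the latter a
#' sequence of `{id, patterns, priority, target}` entries.
#'
#' @param path YAML file path.
#' @return an [intent_registry()].
#' @export
read_intents <- function(path) {
  doc <- yaml::read_yaml(path)
  ints <- lapply(doc$intents, function(x)
    intent(x$id, unlist(x$patterns), isTRUE(x$priority), x$target))
  intent_registry(ints, doc$fallback_id %||% "fallback")
}

#' Write an intent registry to YAML
#' @param registry an [intent_registry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intents <- function(registry, path) {
  doc <- list(fallback_id = registry$fallback_id,
              intents = lapply(unname(registry$intents), function(it)
                compact(list(id = it$intent_id,
                             patterns = as.list(it$patterns),
                             priority = if (it$is_priority) TRUE,
                             target = it$priority_target))))
  writeLines(yaml::as.yaml(doc, indent.mapping.sequence = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a risk lexicon from YAML
#' @param path YAML file path with `self_harm` and `abuse` phrase lists.
#' @return a [risk_lexicon()].
#' @export
read_risk_lexicon <- function(path) {
  doc <- yaml::read_yaml(path)
  risk_lexicon(unlist(doc$self_harm), unlist(doc$abuse) %||% character(0))
}

#' Write a risk lexicon to YAML
#' @param lexicon a [risk_lexicon()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_risk_lexicon <- function(lexicon, path) {
  writeLines(yaml::as.yaml(list(self_harm = as.list(lexicon$self_harm),
                                abuse = as.list(lexicon$abuse)),
                           indent.mapping.sequence = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}
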