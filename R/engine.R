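#' Engine configuration
#'
#' @param max_steps traversal step cap per turn; exceeding it signals a
#'   content bug (e.g. an input-free cycle the validator should have
#'   caught) and raises an engine fault.
#' @param menu_prompt wording of the module menu question.
#' @param finish_label menu option label that routes to the wrap-up module.
#' @param encourage_text extra line shown once the user has completed at
#'   least one module while untried ones remain.
#' @param clarify_text brief line prefixed to a re-prompt after invalid
#'   input; the original prompt is then repeated verbatim.
#' @return an `engine_config` list.
#' @export
engine_config <- function(max_steps = 200,
                          menu_prompt = "What would you like to try?",
                          finish_label = "Finish up",
                          encourage_text = "Nice mahi! Maybe try a skill you haven't tried yet?",
                          clarify_text = "Sorry, I didn't quite catch that.") {
  list(max_steps = max_steps, menu_prompt = menu_prompt,
       finish_label = finish_label, encourage_text = encourage_text,
       clarify_text = clarify_text)
}

out_text <- function(text) list(kind = "text", payload = text, pacing_ms = 0)
out_attachment <- function(att) list(kind = "attachment", payload = att, pacing_ms = 0)

#' User input constructors
#'
#' A turn's input is a small tagged value: typed free text, a tapped quick
#' reply option, an assessment score, or an explicit decline of an
#' optional assessment.
#'
#' @param text,label,score the input value.
#' @return a `user_input` list with fields `kind` and `value`.
#' @name user-input
NULL

#' @rdname user-input
#' @export
ui_text <- function(text) structure(list(kind = "text", value = text), class = "user_input")
#' @rdname user-input
#' @export
ui_option <- function(label) structure(list(kind = "option", value = label), class = "user_input")
#' @rdname user-input
#' @export
ui_score <- function(score) structure(list(kind = "score", value = score), class = "user_input")
#' @rdname user-input
#' @export
ui_decline <- function() structure(list(kind = "decline", value = NULL), class = "user_input")

turn_result <- function(session, outbound) {
  aw <- if (session$ended || is.null(session$awaiting)) list(kind = "none")
        else session$awaiting
  structure(list(outbound = outbound, awaiting = aw,
                 ended = session$ended, session = session),
            class = "turn_result")
}

#' @export
print.turn_result <- function(x, ...) {
  for (m in x$outbound) {
    if (m$kind == "text") cat("bot>", m$payload, "\n")
    else if (m$kind == "attachment")
      cat(sprintf("bot> [%s: %s]\n", m$payload$kind, m$payload$ref))
    else cat("bot> ...typing...\n")
  }
  if (x$ended) cat("-- session ended --\n")
  else cat(sprintf("-- awaiting %s%s --\n", x$awaiting$kind,
                   if (!is.null(x$awaiting$options))
                     paste0(" [", paste(x$awaiting$options, collapse = " | "), "]")
                   else ""))
  invisible(x)
}

log_event <- function(session, type, payload = list()) {
  session$clock <- session$clock + 1L
  ev <- event(iso_time(session$clock_origin + session$clock),
              session$user_id, type, payload)
  session$events[[length(session$events) + 1L]] <- ev
  session
}

#' Start (or resume) a chat session
#'
#' The first-ever session routes through the full onboarding sequence;
#' re-entry (a prior archive is supplied) gets the abbreviated path the
#' content defines for returning users — a greeting plus a repeat of the
#' brief assessment — because the engine exposes the built-in variable
#' `session_index` that the content pack branches on. Saved items,
#' assessment history and module progress carry over from the archive.
#'
#' @param graph a validated `dialog_graph`.
#' @param user_id user identifier.
#' @param prior optional prior `chat_session` (or archive read with
#'   [read_session()]) for a returning user.
#' @param seed integer seed stored on the session (the engine itself is
#'   deterministic; the seed is carried for any downstream sampling).
#' @param registry,lexicon NLU configuration (defaults: shipped registry
#'   and lexicon).
#' @param config an [engine_config()].
#' @param clock_origin seconds offset of this session's logical clock
#'   (used by the simulator to spread users over calendar time).
#' @param check validate the graph before starting (default `TRUE`; batch
#'   callers that already validated once may skip it).
#' @return a `turn_result`; the live session is in `$session`.
#' @export
start_session <- function(graph, user_id, prior = NULL, seed = 0L,
                          registry = default_intents(),
                          lexicon = default_risk_lexicon(),
                          config = engine_config(), clock_origin = NULL,
                          check = TRUE) {
  if (check) {
    issues <- validate_graph(graph)
    if (any(issues$severity == "error"))
      stop_cf("invalid graph: %d validation error(s); run validate_graph()",
              sum(issues$severity == "error"))
  }
  idx <- (prior$session_index %||% 0L) + 1L
  session <- structure(list(
    user_id = user_id, graph_id = graph$graph_id,
    position = NA_character_, variables = list(session_index = idx),
    modules_started = prior$modules_started %||% character(0),
    modules_completed = prior$modules_completed %||% character(0),
    digression_origin = NULL, digression_module = NULL,
    saved_items = prior$saved_items %||% list(),
    assessments = prior$assessments %||% list(),
    session_index = idx, ended = FALSE, rng_seed = as.integer(seed),
    current_module = NULL, awaiting = NULL, escalation = NULL,
    events = list(), trace = character(0),
    clock = prior$clock %||% 0L,
    clock_origin = clock_origin %||% prior$clock_origin %||% 0L),
    class = "chat_session")
  session <- log_event(session, "session_start", list(session_index = idx))
  session <- enter_module(session, graph, graph$entry_module)
  walk_turn(session, graph, list(), config)
}

#' @export
print.chat_session <- function(x, ...) {
  cat(sprintf("<chat_session '%s'> session %d, at '%s'%s\n", x$user_id,
              x$session_index, x$position,
              if (x$ended) " (ended)" else ""))
  cat(sprintf("  modules: %d started, %d completed; %d assessment(s), %d saved item(s)\n",
              length(x$modules_started), length(x$modules_completed),
              length(x$assessments), length(x$saved_items)))
  invisible(x)
}

enter_module <- function(session, graph, module_id) {
  m <- graph$modules[[module_id]]
  if (is.null(m)) stop_cf("unknown module '%s'", module_id)
  session$current_module <- module_id
  session$modules_started <- union(session$modules_started, module_id)
  session$position <- m$entry_node
  log_event(session, "module_start",
            list(module = module_id, session_index = session$session_index))
}

#' Advance a session by one dialog turn
#'
#' Consumes the awaited input (classifying free text, matching quick-reply
#' labels, bounds-checking scores), then traverses the graph — emitting
#' messages and attachments, applying value updates, evaluating branches —
#' until the next node that requires input, a module exit, or session end.
#' Invalid input never crashes the turn: the engine re-prompts with a
#' brief clarification and the original prompt verbatim. Self-harm risk in
#' any typed text preempts all other routing (see [run_escalation()]).
#'
#' @param session the live `chat_session` from the previous `turn_result`.
#' @param graph the dialog graph.
#' @param input a [ui_text()], [ui_option()], [ui_score()] or
#'   [ui_decline()]; required iff the previous turn was awaiting input.
#' @param registry,lexicon NLU configuration.
#' @param config an [engine_config()].
#' @return a `turn_result`.
#' @export
advance_turn <- function(session, graph, input = NULL,
                         registry = default_intents(),
                         lexicon = default_risk_lexicon(),
                         config = engine_config()) {
  if (session$ended) stop_cf("session has ended; no further turns accepted")
  aw <- session$awaiting
  if (is.null(aw) && !is.null(input)) stop_cf("no input is awaited")
  if (!is.null(aw) && is.null(input)) stop_cf("input required: awaiting %s", aw$kind)

  # pending escalation confirmation?
  if (!is.null(session$escalation)) {
    ans <- normalize_text(as.character(input$value %||% ""))
    if (ans %in% c("yes", "y")) return(run_escalation(session, graph, confirm_input = TRUE))
    if (ans %in% c("no", "n"))  return(run_escalation(session, graph, confirm_input = FALSE))
    return(turn_result(session, list(out_text(config$clarify_text),
                                     out_text(graph$escalation$confirm_prompt))))
  }

  outbound <- list()
  if (!is.null(aw)) {
    consumed <- consume_input(session, graph, aw, input, registry, lexicon, config)
    if (!is.null(consumed$turn)) return(consumed$turn) # re-prompt or escalation
    session <- consumed$session
    outbound <- consumed$outbound
  }
  walk_turn(session, graph, outbound, config)
}

# returns list(session=, outbound=) on success or list(turn=) when the turn
# is already complete (re-prompt / escalation started)
consume_input <- function(session, graph, aw, input, registry, lexicon, config) {
  reprompt <- function(session)
    list(turn = turn_result(session, c(list(out_text(config$clarify_text)),
                                       prompt_for(session, graph, aw, config))))
  node <- if (!aw$node_id %in% c("__menu__", "__escalation__"))
    graph$nodes[[aw$node_id]]

  if (aw$kind == "free_text" ||
      (aw$kind == "quick_reply" && identical(input$kind, "text"))) {
    rnode <- node %||% list(type = "quick_replies", out_edges = list())
    dec <- resolve_routing(rnode, input$value, registry, lexicon, graph)
    if (dec$kind == "risk_escalation")
      return(list(turn = run_escalation(session, graph)))
    if (dec$kind == "priority_digression") {
      session <- log_event(session, "intent_detected",
                           list(intent = dec$intent_id,
                                session_index = session$session_index))
      session <- log_event(session, "priority_digression",
                           list(intent = dec$intent_id, from = aw$node_id,
                                to = dec$target,
                                session_index = session$session_index))
      session$digression_origin <- aw$node_id
      tgt_mod <- graph$nodes[[dec$target]]$module_id
      session$digression_module <- tgt_mod
      if (!identical(tgt_mod, session$current_module))
        session <- enter_module(session, graph, tgt_mod)
      session$position <- dec$target # digressions may land mid-module
      session$awaiting <- NULL
      return(list(session = session, outbound = list()))
    }
    if (dec$kind == "local_edge") {
      session <- log_event(session, "intent_detected",
                           list(intent = dec$intent_id,
                                session_index = session$session_index))
      session$position <- dec$target
      session$awaiting <- NULL
      return(list(session = session, outbound = list()))
    }
    # fallback
    if (is.na(dec$target)) return(reprompt(session)) # typed text at quick replies
    session$position <- dec$target
    session$awaiting <- NULL
    return(list(session = session, outbound = list()))
  }

  if (aw$kind == "quick_reply") {
    lbl <- as.character(input$value)
    if (identical(aw$node_id, "__menu__")) {
      target_mod <- aw$menu_map[[lbl]]
      if (is.null(target_mod)) return(reprompt(session))
      session$awaiting <- NULL
      session <- enter_module(session, graph, target_mod)
      return(list(session = session, outbound = list()))
    }
    hit <- Filter(function(e) identical(e$label, lbl), node$out_edges)
    if (!length(hit)) return(reprompt(session))
    session$position <- hit[[1]]$target
    session$awaiting <- NULL
    return(list(session = session, outbound = list()))
  }

  if (aw$kind == "assessment") {
    if (identical(input$kind, "text") &&
        identical(match_risk(input$value, lexicon), "self_harm"))
      return(list(turn = run_escalation(session, graph)))
    if (identical(input$kind, "decline")) {
      if (node$required) return(reprompt(session))
      session$position <- node$out_edges[[1]]$target
      session$awaiting <- NULL
      return(list(session = session, outbound = list()))
    }
    score <- suppressWarnings(as.integer(input$value))
    if (is.na(score) || score < node$scale_min || score > node$scale_max)
      return(reprompt(session))
    session <- record_assessment(session, node, score, graph)
    session$position <- node$out_edges[[1]]$target
    session$awaiting <- NULL
    return(list(session = session, outbound = list()))
  }

  stop_cf("unhandled awaiting kind '%s'", aw$kind)
}

# rebuild the outbound prompt for an awaiting state (used by re-prompts and
# escalation declines)
prompt_for <- function(session, graph, aw, config = engine_config()) {
  if (identical(aw$node_id, "__menu__"))
    return(list(out_text(aw$prompt %||% config$menu_prompt)))
  nd <- graph$nodes[[aw$node_id]]
  switch(nd$type,
    quick_replies = list(out_text(nd$prompt)),
    free_text = list(out_text(nd$prompt)),
    assessment = list(out_text(nd$prompt),
                      out_text(scale_hint(nd))),
    list())
}

scale_hint <- function(nd)
  sprintf("(%d = %s ... %d = %s)", nd$scale_min, nd$anchors[1],
          nd$scale_max, nd$anchors[2])

# traverse until input is required, the menu is shown, or the session ends
walk_turn <- function(session, graph, outbound, config) {
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > config$max_steps)
      stop_cf("engine fault: max_steps (%d) exceeded at node '%s' — content bug?",
              config$max_steps, session$position)
    nd <- graph$nodes[[session$position]]
    if (is.null(nd)) stop_cf("engine fault: position '%s' resolves to no node",
                             session$position)
    session$trace <- c(session$trace, nd$node_id)
    if (!identical(nd$module_id, session$current_module))
      session$current_module <- nd$module_id

    if (nd$type == "message") {
      outbound <- c(outbound, lapply(nd$texts, out_text))
      session$position <- nd$out_edges[[1]]$target

    } else if (nd$type == "rich_media") {
      outbound <- c(outbound, list(out_attachment(nd$attachment)))
      session$position <- nd$out_edges[[1]]$target

    } else if (nd$type == "update_value") {
      session <- apply_update(session, nd)
      session$position <- nd$out_edges[[1]]$target

    } else if (nd$type == "branch") {
      lbl <- evaluate_branch(session, nd)
      hit <- Filter(function(e) identical(e$label, lbl), nd$out_edges)
      if (!length(hit) && lbl == "default")
        stop_cf("engine fault: branch '%s' needs a 'default' edge (variable '%s' unset)",
                nd$node_id, nd$condition$variable)
      session$position <- hit[[1]]$target

    } else if (nd$type == "quick_replies") {
      outbound <- c(outbound, list(out_text(nd$prompt)))
      session$awaiting <- list(kind = "quick_reply", node_id = nd$node_id,
                               options = vapply(nd$out_edges, `[[`, "", "label"))
      return(turn_result(session, outbound))

    } else if (nd$type == "free_text") {
      outbound <- c(outbound, list(out_text(nd$prompt)))
      session$awaiting <- list(kind = "free_text", node_id = nd$node_id)
      return(turn_result(session, outbound))

    } else if (nd$type == "assessment") {
      outbound <- c(outbound, list(out_text(nd$prompt), out_text(scale_hint(nd))))
      session$awaiting <- list(kind = "assessment", node_id = nd$node_id,
                               scale = c(nd$scale_min, nd$scale_max),
                               required = nd$required)
      return(turn_result(session, outbound))

    } else if (nd$type == "exit_module") {
      mod <- nd$module_id
      session$modules_completed <- union(session$modules_completed, mod)
      session <- log_event(session, "module_complete",
                           list(module = mod,
                                session_index = session$session_index))
      if (identical(session$digression_module, mod)) {
        session$digression_origin <- NULL
        session$digression_module <- NULL
      }
      hint <- nd$hint
      if (startsWith(hint, "goto:")) {
        session <- enter_module(session, graph, sub("^goto:", "", hint))
      } else if (hint == "end") {
        session <- log_event(session, "session_end",
                             list(session_index = session$session_index,
                                  reason = "outro"))
        session$ended <- TRUE
        session$awaiting <- NULL
        return(turn_result(session, outbound))
      } else { # menu
        menu <- build_menu(session, graph, config)
        if (is.null(menu)) { # nothing left to offer: end gracefully
          session <- log_event(session, "session_end",
                               list(session_index = session$session_index,
                                    reason = "exhausted"))
          session$ended <- TRUE
          session$awaiting <- NULL
          return(turn_result(session, outbound))
        }
        outbound <- c(outbound, menu$outbound)
        session$awaiting <- menu$awaiting
        return(turn_result(session, outbound))
      }
    } else stop_cf("engine fault: unknown node type '%s'", nd$type)
  }
}

build_menu <- function(session, graph, config) {
  mods <- offer_module_menu(session, graph)
  outro <- Filter(function(m) m$role == "outro", graph$modules)
  if (!length(mods) && !length(outro)) return(NULL)
  titles <- vapply(mods, function(id) graph$modules[[id]]$title, "")
  menu_map <- as.list(mods)
  names(menu_map) <- titles
  if (length(outro)) menu_map[[config$finish_label]] <- outro[[1]]$module_id
  out <- list()
  act_ids <- vapply(Filter(function(m) m$role == "activity", graph$modules),
                    `[[`, "", "module_id")
  if (length(intersect(session$modules_completed, act_ids)) &&
      length(setdiff(mods, session$modules_completed)))
    out <- list(out_text(config$encourage_text))
  out <- c(out, list(out_text(config$menu_prompt)))
  list(outbound = out,
       awaiting = list(kind = "quick_reply", node_id = "__menu__",
                       options = names(menu_map), menu_map = menu_map,
                       prompt = config$menu_prompt))
}

#' Modules currently on offer, in menu order
#'
#' Only activity modules whose serve condition holds are offered. Modules
#' the user has never completed come first (trying new skills is
#' encouraged), completed-but-repeatable ones after; within each band the
#' content pack's order is preserved, so the listing is stable.
#'
#' @param session a `chat_session`.
#' @param graph the dialog graph.
#' @return character vector of module ids.
#' @export
offer_module_menu <- function(session, graph) {
  act <- Filter(function(m) m$role == "activity", graph$modules)
  served <- Filter(function(m) {
    ok <- is.null(m$serve_condition) ||
      isTRUE(eval_condition(session$variables, m$serve_condition))
    ok && (m$repeatable || !m$module_id %in% session$modules_completed)
  }, act)
  ids <- unname(vapply(served, `[[`, "", "module_id"))
  done <- ids %in% session$modules_completed
  c(ids[!done], ids[done])
}

#' Evaluate a branch node against session variables
#'
#' Deterministic: the outcome label is `"true"` or `"false"` from the
#' condition, or `"default"` when the variable is unset under any operator
#' other than `is_set` (or is incomparable, e.g. a non-numeric string
#' under an ordering operator).
#'
#' @param session a `chat_session`.
#' @param node a `branch` node.
#' @return `"true"`, `"false"` or `"default"`.
#' @export
evaluate_branch <- function(session, node) {
  stopifnot(node$type == "branch")
  r <- eval_condition(session$variables, node$condition)
  if (is.na(r)) "default" else if (r) "true" else "false"
}

eval_condition <- function(vars, cond) {
  v <- vars[[cond$variable]]
  if (cond$operator == "is_set") return(!is.null(v))
  if (is.null(v)) return(NA)
  o <- cond$operand
  vn <- suppressWarnings(as.numeric(v))
  on <- suppressWarnings(as.numeric(o))
  numeric_pair <- !is.na(vn) && !is.na(on)
  switch(cond$operator,
    eq = if (numeric_pair) vn == on else identical(as.character(v), as.character(o)),
    ne = if (numeric_pair) vn != on else !identical(as.character(v), as.character(o)),
    lt = if (numeric_pair) vn < on else NA,
    le = if (numeric_pair) vn <= on else NA,
    gt = if (numeric_pair) vn > on else NA,
    ge = if (numeric_pair) vn >= on else NA)
}

#' Apply an update-value node to the session
#'
#' Sets or overwrites a variable. Literal values are taken as-is; the
#' simple expression forms `"var"`, `"var + k"` and `"var - k"` read an
#' existing variable, defaulting it to 0 with a warning when unset.
#'
#' @param session a `chat_session`.
#' @param node an `update_value` node.
#' @return the updated session.
#' @export
apply_update <- function(session, node) {
  stopifnot(node$type == "update_value")
  if (!is.null(node$value)) {
    session$variables[[node$variable]] <- node$value
    return(session)
  }
  m <- regmatches(node$expr,
                  regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(?:([-+])\\s*([0-9]+))?\\s*$",
                          node$expr))[[1]]
  if (!length(m)) stop_cf("update_value '%s': cannot parse expr '%s'",
                          node$node_id, node$expr)
  ref <- session$variables[[m[2]]]
  if (is.null(ref)) {
    warning(sprintf("update_value '%s': variable '%s' unset, defaulting to 0",
                    node$node_id, m[2]), call. = FALSE)
    ref <- 0
  }
  ref <- suppressWarnings(as.numeric(ref))
  if (is.na(ref)) stop_cf("update_value '%s': variable '%s' is not numeric",
                          node$node_id, m[2])
  val <- if (nzchar(m[3])) ref + ifelse(m[3] == "+", 1, -1) * as.numeric(m[4]) else ref
  session$variables[[node$variable]] <- val
  session
}

#' Record an assessment response
#'
#' Appends an assessment record to the session and the event log. The
#' phase is derived from context: `outro` when the item sits in an
#' outro-role module, `onboarding` for the very first administration of a
#' user's first session, `intro` otherwise.
#'
#' @param session a `chat_session`.
#' @param node an `assessment` node.
#' @param score integer score; must lie within the node's scale bounds.
#' @param graph the dialog graph (for module-role lookup).
#' @return the updated session.
#' @export
record_assessment <- function(session, node, score, graph) {
  stopifnot(node$type == "assessment")
  score <- as.integer(score)
  if (is.na(score) || score < node$scale_min || score > node$scale_max)
    stop_cf("score %s outside scale [%d, %d]", score, node$scale_min, node$scale_max)
  role <- graph$modules[[node$module_id]]$role %||% "activity"
  phase <- if (identical(role, "outro")) "outro"
           else if (session$session_index == 1L && !length(session$assessments))
             "onboarding"
           else "intro"
  rec <- list(item_id = node$item_id, phase = phase, score = score,
              session_index = session$session_index)
  session$assessments[[length(session$assessments) + 1L]] <- rec
  log_event(session, "assessment",
            list(item = node$item_id, phase = phase, score = score,
                 session_index = session$session_index))
}

#' Save an attachment for later sessions
#'
#' Posters and other saveable attachments can be kept by the user and are
#' carried across sessions via the session archive. Items are
#' deduplicated by their reference.
#'
#' @param session a `chat_session`.
#' @param attachment an [attachment_ref()]; must be `saveable`.
#' @return the updated session.
#' @export
save_item <- function(session, attachment) {
  stopifnot(inherits(attachment, "attachment_ref"))
  if (!isTRUE(attachment$saveable))
    stop_cf("attachment '%s' is not saveable", attachment$ref)
  refs <- vapply(session$saved_items, `[[`, "", "ref")
  if (!attachment$ref %in% refs)
    session$saved_items[[length(session$saved_items) + 1L]] <- attachment
  session
}

# ---- session archives ------------------------------------------------------

#' Write a session archive
#'
#' A versioned JSON document with everything a later session needs: the
#' session index, saved items, assessment history and module progress.
#' Live traversal state is deliberately not archived — a session resumes
#' at its entry, not mid-node.
#'
#' @param session a `chat_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  doc <- list(schema = "chatflow-session/1",
              user_id = session$user_id, graph_id = session$graph_id,
              session_index = session$session_index,
              modules_started = as.list(session$modules_started),
              modules_completed = as.list(session$modules_completed),
              saved_items = lapply(session$saved_items, unclass),
              assessments = session$assessments,
              clock = session$clock, clock_origin = session$clock_origin)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a session archive written by [write_session()]
#' @param path archive path.
#' @return a list usable as the `prior` argument of [start_session()].
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "chatflow-session/1"))
    stop_cf("unrecognized or corrupt session archive: %s", path)
  doc$modules_started <- unlist(doc$modules_started) %||% character(0)
  doc$modules_completed <- unlist(doc$modules_completed) %||% character(0)
  doc$saved_items <- lapply(doc$saved_items, function(x)
    attachment_ref(x$kind, x$ref, x$caption, isTRUE(x$saveable)))
  doc
}
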