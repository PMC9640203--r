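#' Message pacing configuration
#'
#' Message pacing confers conversational humanness: a short delay before
#' each bubble, preceded by a "typing on" indicator. The delay grows with
#' message length up to a cap. In test mode every delay is zero so suites
#' and replays run instantly; pacing only ever annotates messages — the
#' engine itself never sleeps.
#'
#' @param base_ms fixed delay per message (default 300 ms).
#' @param per_char_ms additional delay per character (default 10 ms).
#' @param cap_ms upper bound on any single delay (default 2000 ms).
#' @param test_mode when `TRUE`, every delay is 0.
#' @return a `pacing_config` list.
#' @export
pacing_config <- function(base_ms = 300, per_char_ms = 10, cap_ms = 2000,
                          test_mode = FALSE) {
  list(base_ms = base_ms, per_char_ms = per_char_ms, cap_ms = cap_ms,
       test_mode = isTRUE(test_mode))
}

#' Compute the pacing delay for one outbound message
#'
#' `delay = min(cap_ms, base_ms + per_char_ms * nchar(text))`; zero in
#' test mode and for typing indicators.
#'
#' @param message an outbound message (list with `kind` and `payload`).
#' @param config a [pacing_config()].
#' @return delay in milliseconds.
#' @export
pacing_delay <- function(message, config = pacing_config()) {
  if (config$test_mode || message$kind == "typing_on") return(0)
  n <- if (message$kind == "text") nchar(message$payload) else 0L
  min(config$cap_ms, config$base_ms + config$per_char_ms * n)
}

#' Annotate outbound messages with pacing
#'
#' Inserts a `typing_on` indicator before each delayed message and fills
#' in `pacing_ms`. Content and ordering are never altered — only delay
#' annotations are added.
#'
#' @param outbound list of outbound messages from a `turn_result`.
#' @param config a [pacing_config()].
#' @return the annotated outbound list.
#' @export
pace_messages <- function(outbound, config = pacing_config()) {
  out <- list()
  for (m in outbound) {
    d <- pacing_delay(m, config)
    if (d > 0)
      out[[length(out) + 1L]] <- list(kind = "typing_on", payload = NULL,
                                      pacing_ms = d)
    m$pacing_ms <- d
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Read a conversation script from YAML
#'
#' A script is a non-empty ordered list of user inputs; each step is one
#' of `text: ...`, `option: ...`, `score: n` or `decline: true`.
#'
#' @param path YAML file path.
#' @return a list of [ui_text()]/[ui_option()]/[ui_score()]/[ui_decline()]
#'   steps.
#' @export
read_script <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!length(doc)) stop_cf("script is empty: %s", path)
  lapply(doc, function(s) {
    if (!is.null(s$text)) ui_text(s$text)
    else if (!is.null(s$option)) ui_option(s$option)
    else if (!is.null(s$score)) ui_score(s$score)
    else if (isTRUE(s$decline)) ui_decline()
    else stop_cf("unrecognized script step: %s", paste(names(s), collapse = ","))
  })
}

#' Replay a script against a graph
#'
#' Drives [start_session()]/[advance_turn()] with the scripted inputs
#' until the script is exhausted or the session ends, producing a
#' transcript: an interleaving of outbound messages and user inputs with
#' turn indices. For a fixed (graph, script, seed) the transcript is
#' byte-identical across runs — inputs the engine rejects appear in the
#' transcript followed by its re-prompt, exactly as a live user would see.
#'
#' @param graph a validated `dialog_graph`.
#' @param script list of input steps (see [read_script()]).
#' @param seed integer seed.
#' @param registry,lexicon NLU configuration.
#' @param config an [engine_config()].
#' @param pacing a [pacing_config()]; default test mode (zero delays).
#' @param prior optional prior session archive.
#' @return a `transcript` object (list of entries; see
#'   [transcript_lines()]).
#' @export
replay_script <- function(graph, script, seed = 0L,
                          registry = default_intents(),
                          lexicon = default_risk_lexicon(),
                          config = engine_config(),
                          pacing = pacing_config(test_mode = TRUE),
                          prior = NULL) {
  entries <- list()
  turn <- 1L
  push_out <- function(tr) {
    for (m in pace_messages(tr$outbound, pacing))
      entries[[length(entries) + 1L]] <<- list(
        turn = turn, dir = "out", kind = m$kind,
        payload = if (m$kind == "attachment") unclass(m$payload) else m$payload,
        pacing_ms = m$pacing_ms)
  }
  tr <- start_session(graph, "replay_user", prior = prior, seed = seed,
                      registry = registry, lexicon = lexicon, config = config)
  push_out(tr)
  for (step in script) {
    if (tr$ended) break
    turn <- turn + 1L
    entries[[length(entries) + 1L]] <- list(turn = turn, dir = "in",
                                            kind = step$kind,
                                            payload = step$value)
    tr <- advance_turn(tr$session, graph, step, registry = registry,
                       lexicon = lexicon, config = config)
    push_out(tr)
  }
  structure(list(entries = entries, session = tr$session, ended = tr$ended),
            class = "transcript")
}

#' Render a transcript as canonical JSON lines
#'
#' One JSON object per line, one line per transcript entry. Two replays
#' of the same (graph, script, seed) yield identical lines; this is the
#' representation written by [write_transcript()].
#'
#' @param transcript a `transcript`.
#' @return character vector of JSON lines.
#' @export
transcript_lines <- function(transcript) {
  vapply(transcript$entries, function(e)
    as.character(jsonlite::toJSON(compact(e), auto_unbox = TRUE)), "")
}

#' Write a transcript to a JSON-lines file
#' @param transcript a `transcript`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  writeLines(transcript_lines(transcript), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.transcript <- function(x, ...) {
  for (e in x$entries) {
    if (e$dir == "in") cat(sprintf("user> %s\n", e$payload))
    else if (e$kind == "text") cat(sprintf("bot>  %s\n", e$payload))
    else if (e$kind == "attachment")
      cat(sprintf("bot>  [%s: %s]\n", e$payload$kind, e$payload$ref))
  }
  invisible(x)
}

#' Run an interactive console session
#'
#' A minimal terminal channel over the same engine contract the scripted
#' channel uses: prompts are printed, input is read from `stdin`, typing
#' indicators become a brief pause unless pacing is in test mode.
#'
#' @inheritParams replay_script
#' @param user_id user identifier for the session.
#' @return the final `chat_session`, invisibly.
#' @export
run_console <- function(graph, user_id = "console_user", seed = 0L,
                        registry = default_intents(),
                        lexicon = default_risk_lexicon(),
                        config = engine_config(),
                        pacing = pacing_config(), prior = NULL) {
  emit <- function(tr) {
    for (m in pace_messages(tr$outbound, pacing)) {
      if (m$kind == "typing_on") { Sys.sleep(m$pacing_ms / 1000); next }
      if (m$kind == "text") cat(m$payload, "\n")
      else cat(sprintf("[%s: %s]\n", m$payload$kind, m$payload$ref))
    }
    if (!tr$ended && !is.null(tr$awaiting$options))
      cat("  options:", paste(tr$awaiting$options, collapse = " | "), "\n")
  }
  tr <- start_session(graph, user_id, prior = prior, seed = seed,
                      registry = registry, lexicon = lexicon, config = config)
  emit(tr)
  con <- file("stdin")
  on.exit(close(con))
  while (!tr$ended) {
    line <- readLines(con, n = 1)
    if (!length(line)) break
    input <- switch(tr$awaiting$kind,
      assessment = if (normalize_text(line) %in% c("skip", "decline"))
        ui_decline() else ui_score(line),
      quick_reply = if (line %in% tr$awaiting$options) ui_option(line)
                    else ui_text(line),
      ui_text(line))
    tr <- advance_turn(tr$session, graph, input, registry = registry,
                       lexicon = lexicon, config = config)
    emit(tr)
  }
  invisible(tr$session)
}
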