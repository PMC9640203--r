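#' Risk escalation wording
#'
#' The fixed four-step protocol run whenever self-harm risk is detected in
#' user input, regardless of dialog position: confirmation, expression of
#' empathy, direction to a help hotline, and shutdown of the automated
#' dialog. All wording is configuration, not code; the shipped defaults are
#' deliberately placeholders (a research artifact must never carry a stale
#' real hotline number).
#'
#' @param confirm_prompt yes/no question confirming the user meant it.
#' @param empathy_text empathetic acknowledgement sent on confirmation.
#' @param hotline_text direction to human help (configure your local
#'   crisis line here).
#' @param decline_return_text sent when the user says it was a false
#'   alarm, before resuming the interrupted dialog.
#' @return an `escalation_config`.
#' @export
escalation_config <- function(
    confirm_prompt = "That sounded serious. Are you thinking about hurting yourself?",
    empathy_text = "I'm really sorry you're feeling this way. You deserve support from a real person.",
    hotline_text = "Please reach out right now: call or text [YOUR LOCAL CRISIS HELPLINE].",
    decline_return_text = "Okay, thanks for letting me know. Let's carry on.") {
  texts <- list(confirm_prompt = confirm_prompt, empathy_text = empathy_text,
                hotline_text = hotline_text,
                decline_return_text = decline_return_text)
  if (any(!nzchar(unlist(texts))))
    stop_cf("escalation_config: all four texts must be non-empty")
  structure(texts, class = "escalation_config")
}

#' Run one step of the risk-escalation protocol
#'
#' Phase 1 (no `confirm_input`): pose the confirmation question and suspend
#' whatever the dialog was awaiting. Phase 2 with `confirm_input = TRUE`:
#' send the empathy and hotline messages, log a `risk_escalation` event and
#' end the session — no further turns are accepted. Phase 2 with
#' `confirm_input = FALSE`: acknowledge and resume the interrupted node by
#' repeating its prompt.
#'
#' Normally invoked by [advance_turn()] when routing decides
#' `risk_escalation`; exposed for direct testing of the protocol.
#'
#' @param session a `chat_session`.
#' @param graph the dialog graph (needed to re-prompt on decline).
#' @param config an [escalation_config()]; defaults to the graph's.
#' @param confirm_input `NULL` for phase 1, else logical answer.
#' @return a `turn_result` (with the updated session in `$session`).
#' @export
run_escalation <- function(session, graph, config = NULL, confirm_input = NULL) {
  config <- config %||% graph$escalation
  if (is.null(confirm_input)) {
    session$escalation <- list(resume = session$awaiting)
    session$awaiting <- list(kind = "quick_reply", node_id = "__escalation__",
                             options = c("yes", "no"))
    return(turn_result(session, list(out_text(config$confirm_prompt))))
  }
  if (isTRUE(confirm_input)) {
    out <- list(out_text(config$empathy_text), out_text(config$hotline_text))
    session <- log_event(session, "risk_escalation",
                         list(category = "self_harm",
                              session_index = session$session_index))
    session <- log_event(session, "session_end",
                         list(session_index = session$session_index,
                              reason = "risk_escalation"))
    session$escalation <- NULL
    session$awaiting <- NULL
    session$ended <- TRUE
    return(turn_result(session, out))
  }
  resume <- session$escalation$resume
  session$escalation <- NULL
  session$awaiting <- resume
  out <- c(list(out_text(config$decline_return_text)),
           prompt_for(session, graph, resume))
  turn_result(session, out)
}
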