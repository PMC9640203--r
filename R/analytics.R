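EVENT_TYPES <- c("registration", "session_start", "module_start",
                 "module_complete", "intent_detected", "priority_digression",
                 "assessment", "risk_escalation", "session_end")

# payload keys that would carry raw user language; their presence is a
# privacy violation and is rejected at construction time
FREE_TEXT_KEYS <- c("text", "free_text", "raw_text", "utterance", "message",
                    "input", "transcript")

#' Create a usage event
#'
#' Usage analytics store only the *series of activities and intents* —
#' which modules were started and completed, which intents fired, which
#' assessments were answered — never what the user actually typed. Any
#' payload key designated as free text is rejected outright, so raw
#' language cannot leak into the research log even by accident.
#'
#' @param timestamp ISO-8601 timestamp string.
#' @param user_id user identifier.
#' @param type one of `r paste(EVENT_TYPES, collapse = ", ")`.
#' @param payload small named list of identifiers/scores (module id,
#'   intent id, phase + score, ...).
#' @return an `event` object.
#' @export
event <- function(timestamp, user_id, type, payload = list()) {
  if (!type %in% EVENT_TYPES)
    stop_cf("unknown event type '%s'", type)
  bad <- intersect(names(payload), FREE_TEXT_KEYS)
  if (length(bad))
    stop_cf("privacy violation: payload key(s) %s would carry raw user text",
            paste(sQuote(bad), collapse = ", "))
  structure(list(timestamp = timestamp, user_id = user_id, type = type,
                 payload = payload),
            class = "event")
}

#' Create an (empty) append-only event log
#' @param events optional list of [event()] objects.
#' @return an `event_log`.
#' @export
event_log <- function(events = list()) {
  stopifnot(all(vapply(events, inherits, TRUE, "event")))
  structure(list(events = events), class = "event_log")
}

#' Append an event to a log
#'
#' The log is append-only; events are re-validated on the way in (the
#' privacy rule is enforced even for events built by hand).
#'
#' @param log an [event_log()].
#' @param ev an [event()].
#' @return the extended log.
#' @export
append_event <- function(log, ev) {
  stopifnot(inherits(log, "event_log"))
  ev <- event(ev$timestamp, ev$user_id, ev$type, ev$payload) # re-validate
  log$events[[length(log$events) + 1L]] <- ev
  log
}

#' @export
length.event_log <- function(x) length(x$events)

#' @export
print.event_log <- function(x, ...) {
  tab <- table(vapply(x$events, `[[`, "", "type"))
  cat(sprintf("<event_log> %d events\n", length(x$events)))
  if (length(tab))
    for (t in names(tab)) cat(sprintf("  %-20s %d\n", t, tab[[t]]))
  invisible(x)
}

#' @export
as.data.frame.event_log <- function(x, ...) {
  pk <- function(ev, key) {
    v <- ev$payload[[key]]
    if (is.null(v)) NA else v
  }
  data.frame(
    timestamp = vapply(x$events, `[[`, "", "timestamp"),
    user_id = vapply(x$events, `[[`, "", "user_id"),
    type = vapply(x$events, `[[`, "", "type"),
    session_index = vapply(x$events, function(e) as.integer(pk(e, "session_index")), 1L),
    module = vapply(x$events, function(e) as.character(pk(e, "module")), ""),
    intent = vapply(x$events, function(e) as.character(pk(e, "intent")), ""),
    item = vapply(x$events, function(e) as.character(pk(e, "item")), ""),
    phase = vapply(x$events, function(e) as.character(pk(e, "phase")), ""),
    score = vapply(x$events, function(e) as.integer(pk(e, "score")), 1L),
    stringsAsFactors = FALSE)
}

#' Write an event log as JSON lines
#' @param log an [event_log()].
#' @param path output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_events <- function(log, path) {
  lines <- vapply(log$events, function(e)
    as.character(jsonlite::toJSON(unclass(e), auto_unbox = TRUE)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an event log written by [write_events()]
#' @param path JSON-lines path.
#' @return an [event_log()].
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  event_log(lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    event(x$timestamp, x$user_id, x$type, x$payload %||% list())
  }))
}

#' Write / read a user table as CSV
#'
#' Columns: `user_id, age, gender, ethnicity, registered_at`.
#'
#' @param users data.frame of user records.
#' @param path CSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_users <- function(users, path) {
  utils::write.csv(users, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_users
#' @export
read_users <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

# first same-session (pre, post) score pair per user; pre = first
# onboarding/intro score of that session, post = first outro score.
# Cross-session pairing is deliberately not attempted.
completer_pairs <- function(edf) {
  a <- edf[edf$type == "assessment" & !is.na(edf$score), , drop = FALSE]
  if (!nrow(a)) return(data.frame(user_id = character(0),
                                  session_index = integer(0),
                                  pre = integer(0), post = integer(0)))
  out <- list()
  for (uid in unique(a$user_id)) {
    ua <- a[a$user_id == uid, , drop = FALSE]
    for (s in sort(unique(ua$session_index))) {
      sa <- ua[ua$session_index == s, , drop = FALSE]
      pre <- sa$score[sa$phase %in% c("onboarding", "intro")]
      post <- sa$score[sa$phase == "outro"]
      if (length(pre) && length(post)) {
        out[[length(out) + 1L]] <- data.frame(
          user_id = uid, session_index = s, pre = pre[1], post = post[1])
        break # first completed pair per user
      }
    }
  }
  if (!length(out)) return(data.frame(user_id = character(0),
                                      session_index = integer(0),
                                      pre = integer(0), post = integer(0)))
  do.call(rbind, out)
}

pct_breakdown <- function(values, digits = 1) {
  n <- length(values)
  if (!n) return(NULL)
  tab <- table(values)
  p <- round_half_up(100 * as.numeric(tab) / n, digits)
  names(p) <- names(tab)
  sort(p, decreasing = TRUE)
}

#' Summarize an open-trial cohort
#'
#' Reproduces the standard uptake arithmetic for a chatbot open trial:
#' registrations, logins, the target-age subset (inclusive age bounds),
#' gender and ethnicity percentage breakdowns over target-age users,
#' pre/post completion among those who reached the session wrap-up, the
#' pre/post worry-score means and SDs, and the count of returning users.
#' Percentages are rounded half-up to 1 decimal (completion percentage to
#' 0 decimals, matching the convention of reporting it as an integer).
#'
#' @param log an [event_log()].
#' @param users data.frame of user records (`user_id, age, gender,
#'   ethnicity`, optionally `registered_at`).
#' @param target_age inclusive age range, default `c(13, 24)`.
#' @param outro_module module id whose `module_start` event marks "reached
#'   the outro offer" (default `"outro"`).
#' @return a `cohort_summary` list; see Details for fields.
#' @details Fields: `n_registered`, `n_logged_in`, `n_target_age`,
#'   `pct_by_gender`, `pct_by_ethnicity` (named vectors over target-age
#'   users), `prepost_denominator` (target-age users with at least one
#'   pre score who reached the outro offer), `n_prepost_completers`,
#'   `pct_prepost`, `mean_pre`, `sd_pre`, `mean_post`, `sd_post`
#'   (over completers, 1 decimal), `n_returned` (target-age users with 2+
#'   sessions).
#' @export
summarize_cohort <- function(log, users, target_age = c(13, 24),
                             outro_module = "outro") {
  edf <- as.data.frame(log)
  known <- unique(edf$user_id)
  if (length(setdiff(known, users$user_id)))
    stop_cf("event log mentions user(s) absent from the user table")
  n_registered <- nrow(users)
  logged <- unique(edf$user_id[edf$type == "session_start"])
  in_range <- users$age >= target_age[1] & users$age <= target_age[2]
  target <- users[users$user_id %in% logged & in_range, , drop = FALSE]

  tedf <- edf[edf$user_id %in% target$user_id, , drop = FALSE]
  has_pre <- unique(tedf$user_id[tedf$type == "assessment" &
                                   tedf$phase %in% c("onboarding", "intro")])
  reached <- unique(tedf$user_id[tedf$type == "module_start" &
                                   tedf$module == outro_module])
  denom_users <- intersect(has_pre, reached)
  pairs <- completer_pairs(tedf[tedf$user_id %in% denom_users, , drop = FALSE])
  pp <- prepost_stats(pairs)

  sess_counts <- table(unique(tedf[tedf$type == "session_start",
                                   c("user_id", "session_index")])$user_id)
  structure(list(
    n_registered = n_registered,
    n_logged_in = length(logged),
    n_target_age = nrow(target),
    pct_by_gender = pct_breakdown(target$gender),
    pct_by_ethnicity = pct_breakdown(target$ethnicity),
    prepost_denominator = length(denom_users),
    n_prepost_completers = nrow(pairs),
    pct_prepost = if (length(denom_users))
      round_half_up(100 * nrow(pairs) / length(denom_users), 0),
    mean_pre = pp$mean_pre, sd_pre = pp$sd_pre,
    mean_post = pp$mean_post, sd_post = pp$sd_post,
    n_returned = sum(sess_counts >= 2)),
    class = "cohort_summary")
}

prepost_stats <- function(pairs) {
  n <- nrow(pairs)
  r1 <- function(x) round_half_up(x, 1)
  list(n = n,
       mean_pre = if (n) r1(mean(pairs$pre)),
       sd_pre = if (n > 1) r1(stats::sd(pairs$pre)),
       mean_post = if (n) r1(mean(pairs$post)),
       sd_post = if (n > 1) r1(stats::sd(pairs$post)))
}

#' Pre/post worry-score summary over completers
#'
#' Means and sample standard deviations (n-1 denominator) of the pre and
#' post scores of users who recorded both within one session: the pre
#' score is the first onboarding/intro score of the session containing
#' the completed pair, the post score the first outro score of that same
#' session. Values are rounded half-up to 1 decimal. With no completers
#' the values are absent (`NULL`), not zero; with a single completer the
#' SDs are absent.
#'
#' @param log an [event_log()].
#' @param users optional data.frame of user records; when given together
#'   with `target_age`, scores are restricted to target-age users.
#' @param target_age inclusive age range filter, default `c(13, 24)`.
#' @return a list with `mean_pre`, `sd_pre`, `mean_post`, `sd_post`, `n`.
#' @export
prepost_summary <- function(log, users = NULL, target_age = c(13, 24)) {
  edf <- as.data.frame(log)
  if (!is.null(users)) {
    keep <- users$user_id[users$age >= target_age[1] & users$age <= target_age[2]]
    edf <- edf[edf$user_id %in% keep, , drop = FALSE]
  }
  prepost_stats(completer_pairs(edf))
}

#' @export
print.cohort_summary <- function(x, ...) {
  row <- function(k, v) cat(sprintf("  %-26s %s\n", k, v))
  fmt <- function(v) if (is.null(v)) "-" else format(v)
  cat("Cohort summary\n")
  row("registered", x$n_registered)
  row("logged in", x$n_logged_in)
  row("target age (13-24)", x$n_target_age)
  for (nm in names(x$pct_by_gender))
    row(paste0("  gender: ", nm), sprintf("%.1f%%", x$pct_by_gender[[nm]]))
  for (nm in names(x$pct_by_ethnicity))
    row(paste0("  ethnicity: ", nm), sprintf("%.1f%%", x$pct_by_ethnicity[[nm]]))
  row("pre/post denominator", x$prepost_denominator)
  row("pre/post completers",
      sprintf("%d (%s%%)", x$n_prepost_completers, fmt(x$pct_prepost)))
  row("worry pre mean (SD)", sprintf("%s (%s)", fmt(x$mean_pre), fmt(x$sd_pre)))
  row("worry post mean (SD)", sprintf("%s (%s)", fmt(x$mean_post), fmt(x$sd_post)))
  row("returned (2+ sessions)", x$n_returned)
  invisible(x)
}

#' Serialize a cohort summary to JSON
#' @param summary a `cohort_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(lapply(unclass(summary), function(v)
    if (is.null(v)) NULL else if (!is.null(names(v))) as.list(v) else v),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
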