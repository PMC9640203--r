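# compact constructors for hand-built logs
ev <- function(user, type, ..., t = "2020-04-07T00:00:00Z")
  event(t, user, type, list(...))

mk_log <- function(...) event_log(list(...))

test_that("event payloads can never carry raw user text", {
  log <- event_log()
  log <- append_event(log, ev("u1", "module_complete",
                              module = "practice_gratitude"))
  log <- append_event(log, ev("u1", "intent_detected", intent = "fear"))
  expect_length(log, 2)
  expect_error(append_event(log, ev("u1", "intent_detected",
                                    text = "I feel terrible")),
               "privacy")
  expect_error(event("2020-04-07T00:00:00Z", "u1", "intent_detected",
                     list(utterance = "raw words")), "privacy")
  expect_error(ev("u1", "made_up_type"), "unknown event type")
})

test_that("serialized logs never contain text fed to the chatbot", {
  tr <- demo_at_free_text()
  tr <- advance_turn(tr$session, demo, ui_text(sentinel_text),
                     registry = registry, lexicon = lexicon)
  tr <- advance_turn(tr$session, demo, ui_option("Stay connected"),
                     registry = registry, lexicon = lexicon)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_events(event_log(tr$session$events), tmp)
  raw <- paste(readLines(tmp, warn = FALSE), collapse = "\n")
  for (word in strsplit(sentinel_text, " ")[[1]])
    expect_false(grepl(word, raw, fixed = TRUE), label = word)
})

# a user whose session carries a pre score, an outro offer and optionally
# a post score
user_session_events <- function(user, pre = NULL, outro = FALSE, post = NULL,
                                session = 1L) {
  out <- list(ev(user, "session_start", session_index = session))
  if (!is.null(pre))
    out <- c(out, list(ev(user, "assessment", item = "worry",
                          phase = if (session == 1L) "onboarding" else "intro",
                          score = pre, session_index = session)))
  if (outro)
    out <- c(out, list(ev(user, "module_start", module = "outro",
                          session_index = session)))
  if (!is.null(post))
    out <- c(out, list(ev(user, "assessment", item = "worry", phase = "outro",
                          score = post, session_index = session)))
  out
}

test_that("cohort percentages reproduce worked-example arithmetic", {
  # 127 target-age logins: 90 female, 60 NZ European; 81 reach the outro
  # with a pre score; 30 also record the recheck
  n <- 127
  users <- data.frame(
    user_id = sprintf("u%03d", 1:n),
    age = rep(13:24, length.out = n),
    gender = c(rep("female", 90), rep("male", 37)),
    ethnicity = c(rep("nz_european", 60), rep("other", 67)),
    stringsAsFactors = FALSE)
  events <- list()
  for (i in 1:n)
    events <- c(events, user_session_events(
      users$user_id[i], pre = 5L, outro = i <= 81,
      post = if (i <= 30) 4L))
  s <- summarize_cohort(event_log(events), users)
  expect_identical(s$n_target_age, 127L)
  expect_identical(unname(s$pct_by_gender["female"]), 70.9)
  expect_identical(unname(s$pct_by_ethnicity["nz_european"]), 47.2)
  expect_identical(s$prepost_denominator, 81L)
  expect_identical(s$n_prepost_completers, 30L)
  expect_identical(s$pct_prepost, 37)
})

test_that("pre/post summary does hand arithmetic and handles degeneracy", {
  events <- c(user_session_events("a", pre = 4L, outro = TRUE, post = 3L),
              user_session_events("b", pre = 6L, outro = TRUE, post = 5L))
  pp <- prepost_summary(event_log(events))
  expect_identical(pp$n, 2L)
  expect_identical(pp$mean_pre, 5.0)
  expect_identical(pp$mean_post, 4.0)
  # single completer: SDs are absent, not zero
  pp1 <- prepost_summary(event_log(user_session_events("a", pre = 4L,
                                                       outro = TRUE,
                                                       post = 3L)))
  expect_identical(pp1$n, 1L)
  expect_null(pp1$sd_pre)
  expect_identical(pp1$mean_pre, 4.0)
  # no completers: absent values
  pp0 <- prepost_summary(event_log(user_session_events("a", pre = 4L)))
  expect_identical(pp0$n, 0L)
  expect_null(pp0$mean_pre)
})

test_that("pre/post pairing uses the same session only", {
  # pre in session 1, post in session 2: never paired
  events <- c(user_session_events("a", pre = 7L, session = 1L),
              user_session_events("a", outro = TRUE, post = 2L, session = 2L))
  expect_identical(prepost_summary(event_log(events))$n, 0L)
  # the completed pair's session defines the pre score
  events2 <- c(user_session_events("b", pre = 9L, session = 1L),
               user_session_events("b", pre = 3L, outro = TRUE, post = 2L,
                                   session = 2L))
  pp <- prepost_summary(event_log(events2))
  expect_identical(pp$n, 1L)
  expect_identical(pp$mean_pre, 3.0)
})

test_that("empty cohorts summarize to zeros with absent percentages", {
  users <- data.frame(user_id = character(0), age = integer(0),
                      gender = character(0), ethnicity = character(0))
  s <- summarize_cohort(event_log(), users)
  expect_identical(s$n_registered, 0L)
  expect_identical(s$n_target_age, 0L)
  expect_null(s$pct_by_gender)
  expect_null(s$pct_prepost)
  expect_null(s$mean_pre)
})

test_that("summaries agree with a brute-force pass over raw events", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    users <- data.frame(
      user_id = sprintf("r%02d", 1:n),
      age = sample(10:40, n, TRUE),
      gender = sample(c("female", "male", "another"), n, TRUE),
      ethnicity = sample(c("nz_european", "maori", "other"), n, TRUE),
      stringsAsFactors = FALSE)
    events <- list()
    truth <- list(logged = character(0), pre = list(), reached = character(0),
                  post = list())
    for (i in 1:n) {
      if (runif(1) < 0.2) next # never logs in
      truth$logged <- c(truth$logged, users$user_id[i])
      pre <- if (runif(1) < 0.8) sample(0:10, 1)
      outro <- runif(1) < 0.6
      post <- if (outro && runif(1) < 0.5) sample(0:10, 1)
      if (outro) truth$reached <- c(truth$reached, users$user_id[i])
      if (!is.null(pre)) truth$pre[[users$user_id[i]]] <- pre
      if (!is.null(pre) && !is.null(post))
        truth$post[[users$user_id[i]]] <- c(pre, post)
      events <- c(events, user_session_events(users$user_id[i], pre = pre,
                                              outro = outro, post = post))
    }
    s <- summarize_cohort(event_log(events), users)
    in_range <- users$age >= 13 & users$age <= 24
    target <- users$user_id[in_range & users$user_id %in% truth$logged]
    expect_identical(s$n_logged_in, length(truth$logged))
    expect_identical(s$n_target_age, length(target))
    denom <- intersect(intersect(names(truth$pre), truth$reached), target)
    expect_identical(s$prepost_denominator, length(denom))
    completers <- intersect(names(truth$post), target)
    expect_identical(s$n_prepost_completers, length(completers))
    if (length(completers)) {
      pres <- vapply(truth$post[completers], `[`, 1L, 1)
      expect_identical(s$mean_pre, round_half_up(mean(pres), 1))
    }
  }
})

test_that("digression events in a replay match routing decisions one-for-one", {
  script <- list(ui_option("Let's go"), ui_score(5),
                 ui_text("so bored today"),     # priority: no local edge
                 ui_option("Practice gratitude"),
                 ui_text("feeling nervous"),    # priority at gratitude prompt
                 ui_option("Finish up"), ui_decline(), ui_option("\U0001F60A"))
  tr <- replay_script(demo, script, seed = 1, registry = registry,
                      lexicon = lexicon)
  types <- vapply(tr$session$events, `[[`, "", "type")
  # independent count: run the router over the same (node, text) pairs
  expected <- sum(
    resolve_routing(graph_node(demo, "ii_feel"), "so bored today",
                    registry, lexicon, demo)$kind == "priority_digression",
    resolve_routing(graph_node(demo, "pg_prompt"), "feeling nervous",
                    registry, lexicon, demo)$kind == "priority_digression")
  expect_identical(sum(types == "priority_digression"), expected)
  expect_identical(expected, 2L)
})

test_that("event logs round-trip through JSON lines", {
  log <- mk_log(ev("u1", "session_start", session_index = 1L),
                ev("u1", "assessment", item = "worry", phase = "onboarding",
                   score = 5L, session_index = 1L))
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_events(log, tmp)
  log2 <- read_events(tmp)
  expect_identical(as.data.frame(log2), as.data.frame(log))
})
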