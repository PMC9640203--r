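adv <- function(tr, input = NULL)
  advance_turn(tr$session, demo, input, registry = registry, lexicon = lexicon)

test_that("first sessions onboard fully; re-entry is abbreviated", {
  tr1 <- start_session(demo, "ana", registry = registry, lexicon = lexicon)
  expect_false(tr1$ended)
  expect_identical(tr1$awaiting$kind, "quick_reply") # consent question
  expect_gt(length(tr1$outbound), 3) # intro messages + selfie + onboarding
  n_first <- length(tr1$outbound)

  # play to the assessment so the archive is realistic, then re-enter
  tr <- adv(tr1, ui_option("Let's go"))
  expect_identical(tr$awaiting$kind, "assessment")
  tr2 <- start_session(demo, "ana", prior = tr$session,
                       registry = registry, lexicon = lexicon)
  expect_identical(tr2$session$session_index, 2L)
  expect_lt(length(tr2$outbound), n_first)
  # first input request on re-entry is the brief assessment itself
  expect_identical(tr2$awaiting$kind, "assessment")
  expect_identical(graph_node(demo, tr2$awaiting$node_id)$item_id, "worry")
})

test_that("identical inputs give identical turn results", {
  run <- function() {
    tr <- start_session(demo, "bo", seed = 11,
                        registry = registry, lexicon = lexicon)
    tr <- adv(tr, ui_option("Let's go"))
    tr <- adv(tr, ui_score(6))
    tr$outbound
  }
  expect_identical(run(), run())
})

test_that("branch evaluation matches a brute-force operator table", {
  mk <- function(var, op, operand)
    branch_node("b", condition(var, op, operand), true = "t", false = "f",
                default = "d")
  sess <- function(vars) list(variables = vars)
  # exhaustive over all six comparison operators x small operand grid
  for (op in c("eq", "ne", "lt", "le", "gt", "ge")) {
    for (x in 0:4) {
      for (o in 0:4) {
        want <- switch(op, eq = x == o, ne = x != o, lt = x < o,
                       le = x <= o, gt = x > o, ge = x >= o)
        got <- evaluate_branch(sess(list(x = x)), mk("x", op, o))
        expect_identical(got, if (want) "true" else "false",
                         label = sprintf("%d %s %d", x, op, o))
      }
    }
    # unset variable -> default, for every operator except is_set
    expect_identical(evaluate_branch(sess(list()), mk("x", op, 1)), "default")
  }
  expect_identical(evaluate_branch(sess(list(x = 5)), mk("x", "ge", 3)), "true")
  # strings that look numeric compare numerically
  expect_identical(evaluate_branch(sess(list(x = "4")), mk("x", "eq", "4")),
                   "true")
  expect_identical(evaluate_branch(sess(list()), mk("x", "is_set", NULL)),
                   "false")
})

test_that("update nodes set, overwrite and increment variables", {
  s <- list(variables = list())
  s <- apply_update(s, update_value_node("u1", "worry_pre", value = 7L, to = "z"))
  expect_identical(s$variables$worry_pre, 7L)
  s <- apply_update(s, update_value_node("u2", "worry_pre", value = 3L, to = "z"))
  expect_identical(s$variables$worry_pre, 3L)
  s$variables$counter <- 2
  s <- apply_update(s, update_value_node("u3", "counter",
                                         expr = "counter + 1", to = "z"))
  expect_identical(s$variables$counter, 3)
  # unset reference defaults to 0 with a warning
  expect_warning(
    s <- apply_update(s, update_value_node("u4", "n", expr = "m + 1", to = "z")),
    "unset")
  expect_identical(s$variables$n, 1)
})

test_that("branch traversal is invisible and condition-driven", {
  g <- dialog_graph("g", modules = list(
    dialog_module("m1", "m", "u", nodes = list(
      update_value_node("u", "lockdown_level", value = "4", to = "b"),
      branch_node("b", condition("lockdown_level", "eq", "4"),
                  true = "yes", false = "no", default = "no"),
      message_node("yes", "stay home", to = "x"),
      message_node("no", "go out", to = "x"),
      exit_module_node("x", "end")))), entry_module = "m1")
  tr <- start_session(g, "u1", registry = registry, lexicon = lexicon)
  texts <- vapply(tr$outbound, `[[`, "", "payload")
  expect_identical(texts, "stay home") # no output from update/branch
  expect_true(tr$ended)
})

test_that("quick replies route by label, including emoji, and re-prompt on junk", {
  tr <- start_session(demo, "cy", registry = registry, lexicon = lexicon)
  tr <- adv(tr, ui_option("Let's go"))
  tr <- adv(tr, ui_score(2))
  tr <- adv(tr, ui_text("all good"))
  tr <- adv(tr, ui_option("Get active"))
  expect_identical(tr$awaiting$options, c("\U0001F60A", "\U0001F610", "\U0001F61E"))
  # invalid label: re-prompt (clarification + same prompt), same awaiting
  tr_bad <- adv(tr, ui_option("banana"))
  expect_false(tr_bad$ended)
  expect_identical(tr_bad$awaiting$node_id, tr$awaiting$node_id)
  expect_identical(length(tr_bad$outbound), 2L)
  expect_identical(tr_bad$outbound[[2]]$payload,
                   graph_node(demo, tr$awaiting$node_id)$prompt)
  # the sad-face option routes like any other label
  tr2 <- adv(tr_bad, ui_option("\U0001F61E"))
  expect_true("ga_ack" %in% tr2$session$trace)
})

test_that("unmapped non-priority intents take the fallback edge", {
  tr <- demo_at_free_text()
  expect_identical(tr$awaiting$kind, "free_text")
  tr2 <- adv(tr, ui_text("thinking about my playlist")) # music: no local edge
  expect_true("ii_ok" %in% tr2$session$trace) # generic response node
})

test_that("the module menu orders untried before completed and honors gating", {
  tr <- demo_at_free_text()
  tr <- adv(tr, ui_text("ok"))
  menu1 <- offer_module_menu(tr$session, demo)
  acts <- Filter(function(m) m$role == "activity", demo$modules)
  expect_identical(menu1, unname(vapply(acts, `[[`, "", "module_id")))
  # complete one module: it moves to the back but stays selectable
  tr <- adv(tr, ui_option("Practice gratitude"))
  tr <- adv(tr, ui_text("sunshine"))
  menu2 <- offer_module_menu(tr$session, demo)
  expect_identical(menu2[length(menu2)], "practice_gratitude")
  expect_setequal(menu2, menu1)
  expect_true("Practice gratitude" %in% tr$awaiting$options)
  # serve_condition gates a module out until its variable is set
  g <- build_demo_graph()
  g$modules[["money_worries"]]$serve_condition <-
    condition("money_worry", "is_set")
  s <- tr$session
  expect_false("money_worries" %in% offer_module_menu(s, g))
  s$variables$money_worry <- 1
  expect_true("money_worries" %in% offer_module_menu(s, g))
})

test_that("assessments record with the right phase, bounds and decline rules", {
  tr <- start_session(demo, "dee", registry = registry, lexicon = lexicon)
  tr <- adv(tr, ui_option("Let's go"))
  # out-of-bounds score: rejected, nothing recorded, same node re-prompted
  tr_bad <- adv(tr, ui_score(11))
  expect_length(tr_bad$session$assessments, 0)
  expect_identical(tr_bad$awaiting$node_id, tr$awaiting$node_id)
  tr <- adv(tr_bad, ui_score(5))
  expect_identical(tr$session$assessments[[1]]$phase, "onboarding")
  expect_identical(tr$session$assessments[[1]]$score, 5L)
  # second session: intro phase
  tr2 <- start_session(demo, "dee", prior = tr$session,
                       registry = registry, lexicon = lexicon)
  tr2 <- adv(tr2, ui_score(4))
  recs <- tr2$session$assessments
  expect_identical(recs[[length(recs)]]$phase, "intro")
  # outro is optional: declining records nothing
  tr3 <- adv(tr2, ui_option("Finish up"))
  expect_identical(tr3$awaiting$kind, "assessment")
  n_before <- length(tr3$session$assessments)
  tr3 <- adv(tr3, ui_decline())
  expect_length(tr3$session$assessments, n_before)
  expect_identical(tr3$awaiting$kind, "quick_reply") # feedback question
})

test_that("saved items deduplicate, persist, and refuse non-saveable media", {
  poster <- attachment_ref("poster", "assets/tips_reduce_stress.png",
                           saveable = TRUE)
  tr <- start_session(demo, "eli", registry = registry, lexicon = lexicon)
  s <- save_item(tr$session, poster)
  s <- save_item(s, poster)
  expect_length(s$saved_items, 1)
  expect_error(save_item(s, attachment_ref("webview", "a.html",
                                           saveable = FALSE)),
               "not saveable")
  # persists across sessions via the archive
  tmp <- withr::local_tempfile(fileext = ".json")
  write_session(s, tmp)
  tr2 <- start_session(demo, "eli", prior = read_session(tmp),
                       registry = registry, lexicon = lexicon)
  expect_length(tr2$session$saved_items, 1)
  expect_identical(tr2$session$saved_items[[1]]$ref, poster$ref)
})

test_that("every turn terminates and awaiting/ended stay exclusive", {
  set.seed(303)
  for (rep in 1:5) {
    tr <- start_session(demo, paste0("p", rep),
                        registry = registry, lexicon = lexicon)
    for (step in 1:40) {
      aw <- tr$awaiting
      expect_identical(aw$kind == "none", tr$ended)
      if (tr$ended) break
      input <- switch(aw$kind,
        assessment = ui_score(sample(0:10, 1)),
        quick_reply = ui_option(sample(aw$options, 1)),
        free_text = ui_text(sample(c("ok", "happy", "meh"), 1)))
      tr <- advance_turn(tr$session, demo, input,
                         registry = registry, lexicon = lexicon)
    }
  }
})

test_that("modules count as completed only after their exit node", {
  tr <- demo_at_free_text()
  s <- tr$session
  expect_true("introductory_information" %in% s$modules_started)
  expect_false("introductory_information" %in% s$modules_completed)
  tr <- adv(tr, ui_text("ok")) # crosses ii_exit
  expect_true("introductory_information" %in% tr$session$modules_completed)
  expect_true(all(tr$session$modules_completed %in%
                    tr$session$modules_started))
})

test_that("the engine's visited sequence matches a naive interpreter", {
  for (seed in 1:10) {
    g <- random_walk_graph(seed)
    set.seed(seed * 100)
    ref <- naive_interpret(g, choose = function(nd) {
      labels <- vapply(nd$out_edges, `[[`, "", "label")
      sample(labels, 1)
    })
    tr <- start_session(g, "w", registry = registry, lexicon = lexicon)
    for (inp in ref$inputs)
      tr <- advance_turn(tr$session, g, ui_option(inp),
                         registry = registry, lexicon = lexicon)
    expect_true(tr$ended, label = sprintf("seed %d ends", seed))
    expect_identical(tr$session$trace, ref$visited,
                     label = sprintf("visited sequence, seed %d", seed))
  }
})

test_that("input-free cycles trip the step cap as an engine fault", {
  g <- dialog_graph("g", modules = list(
    dialog_module("m1", "m", "a", nodes = list(
      message_node("a", "ping", to = "b"),
      message_node("b", "pong", to = "a"),
      exit_module_node("x", "end")))), entry_module = "m1")
  # the validator flags this content; bypass it to exercise the engine guard
  expect_true("input_free_cycle" %in% validate_graph(g)$code)
  expect_error(start_session(g, "z", check = FALSE,
                             registry = registry, lexicon = lexicon),
               "max_steps")
})

test_that("input protocol violations are errors, not silent misbehavior", {
  tr <- start_session(demo, "fi", registry = registry, lexicon = lexicon)
  expect_error(advance_turn(tr$session, demo, NULL,
                            registry = registry, lexicon = lexicon),
               "input required")
  g <- tiny_graph()
  tr2 <- start_session(g, "fi2", registry = registry, lexicon = lexicon)
  expect_true(tr2$ended)
  expect_error(advance_turn(tr2$session, g, ui_text("hi"),
                            registry = registry, lexicon = lexicon),
               "ended")
})
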