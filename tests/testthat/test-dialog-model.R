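test_that("a minimal document parses to the smallest legal graph", {
  g <- parse_graph(tiny_yaml())
  expect_s3_class(g, "dialog_graph")
  expect_length(g$modules, 1)
  expect_length(g$nodes, 2)
  expect_identical(g$entry_module, "m1")
})

test_that("unresolved references are errors, never partial graphs", {
  bad <- sub("to: x1", "to: nowhere", tiny_yaml(), fixed = TRUE)
  expect_error(parse_graph(bad), "nowhere")
  expect_error(parse_graph(sub("entry_module: m1", "entry_module: zz",
                               tiny_yaml(), fixed = TRUE)), "entry")
  expect_error(parse_graph("modules: ["), "syntax")
  expect_error(parse_graph(sub("type: message", "type: mystery",
                               tiny_yaml(), fixed = TRUE)), "unknown node type")
})

test_that("duplicate identifiers are rejected at construction", {
  expect_error(dialog_graph("g", modules = list(
    dialog_module("m1", "a", "n1", list(message_node("n1", "x", "n1"))),
    dialog_module("m1", "b", "n2", list(message_node("n2", "x", "n2")))),
    entry_module = "m1"), "duplicate module")
  expect_error(dialog_graph("g", modules = list(
    dialog_module("m1", "a", "n1", list(message_node("n1", "x", "n1"),
                                        message_node("n1", "y", "n1")))),
    entry_module = "m1"), "duplicate node")
})

test_that("the packaged demo pack parses with the expected module inventory", {
  g <- parse_graph(chatflow_fixture("demo_graph.yaml"))
  acts <- Filter(function(m) m$role == "activity", g$modules)
  initial <- Filter(function(m) !m$added_post_launch, acts)
  expect_identical(
    vapply(initial, `[[`, "", "title"),
    c(stay_connected = "Stay connected", calming_activities = "Calming activities",
      practice_gratitude = "Practice gratitude", spirituality = "Spirituality",
      distract_yourself = "Distract yourself", get_active = "Get active",
      get_expert_help = "Get expert help", general_tips = "General tips",
      self_care = "Self-care", have_a_routine = "Have a routine",
      protect_your_sleep = "Protect your sleep",
      alcohol_and_drugs = "Alcohol and drugs"))
  expect_true(graph_equal(g, build_demo_graph()))
})

test_that("serialization round-trips and is canonical", {
  g <- tiny_graph()
  expect_true(graph_equal(g, parse_graph(serialize_graph(g))))
  # demo pack: module count and every edge label preserved
  g2 <- parse_graph(serialize_graph(demo))
  expect_length(g2$modules, length(demo$modules))
  labels <- function(g) sort(unlist(lapply(g$nodes, function(nd)
    vapply(nd$out_edges, `[[`, "", "label"))))
  expect_identical(labels(g2), labels(demo))
  # byte-identical on repeat
  expect_identical(serialize_graph(g2), serialize_graph(demo))
})

test_that("parse/serialize is the identity over random valid graphs", {
  for (seed in 1:12) {
    g <- random_full_graph(seed)
    y <- serialize_graph(g)
    g2 <- parse_graph(y)
    expect_true(graph_equal(g, g2), label = sprintf("round trip, seed %d", seed))
    expect_identical(serialize_graph(g2), y,
                     label = sprintf("canonical, seed %d", seed))
  }
})

test_that("the demo pack validates clean", {
  expect_identical(nrow(validate_graph(demo)), 0L)
})

test_that("each seeded defect class is detected with its code", {
  # unrouted quick-reply option: delete one edge, keep the option label
  g <- build_demo_graph()
  g$nodes[["onb_consent"]]$out_edges <- g$nodes[["onb_consent"]]$out_edges[2]
  iss <- validate_graph(g)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "unrouted_option")
  expect_identical(iss$location, "onb_consent")

  # free-text node that lost its fallback edge
  g <- build_demo_graph()
  keep <- vapply(g$nodes[["ii_feel"]]$out_edges, `[[`, "", "label") != "fallback"
  g$nodes[["ii_feel"]]$out_edges <- g$nodes[["ii_feel"]]$out_edges[keep]
  expect_true("missing_fallback" %in% validate_graph(g)$code)

  # missing module entry
  g <- build_demo_graph()
  g$modules[["outro"]]$entry_node <- "ghost"
  expect_true("missing_module_entry" %in% validate_graph(g)$code)

  # dangling priority binding
  g <- build_demo_graph()
  g$priority_bindings[["boredom"]] <- "ghost"
  expect_true("dangling_priority_binding" %in% validate_graph(g)$code)

  # unresolved edge target
  g <- build_demo_graph()
  g$nodes[["sc_tip"]]$out_edges[[1]]$target <- "ghost"
  expect_true("unresolved_target" %in% validate_graph(g)$code)

  # unreachable exit: cut the only path from entry to this module's exit
  g <- build_demo_graph()
  g$nodes[["spirituality_1"]]$out_edges[[1]]$target <- "spirituality_1x"
  g$nodes[["spirituality_1x"]] <- local({
    nd <- message_node("spirituality_1x", "loop", to = "spirituality_1")
    nd$module_id <- "spirituality"
    nd
  })
  iss <- validate_graph(g)
  expect_true("no_reachable_exit" %in% iss$code)
  expect_true("spirituality" %in% iss$location[iss$code == "no_reachable_exit"])
  # ... and that same mutation created an input-free cycle
  expect_true("input_free_cycle" %in% iss$code)

  # orphan node
  g <- build_demo_graph()
  g$nodes[["lost"]] <- local({
    nd <- message_node("lost", "hello?", to = "sc_x")
    nd$module_id <- "stay_connected"
    nd
  })
  iss <- validate_graph(g)
  expect_identical(iss$severity[iss$code == "orphan_node"], "warning")

  # branch without a default edge
  g <- dialog_graph("g", modules = list(
    dialog_module("m1", "a", "b1", list(
      branch_node("b1", condition("x", "eq", 1), true = "x1", false = "x1"),
      exit_module_node("x1", "end")))), entry_module = "m1")
  expect_true("branch_missing_default" %in% validate_graph(g)$code)

  # cross-module edge warning
  g <- build_demo_graph()
  g$nodes[["sc_tip"]]$out_edges[[1]]$target <- "ga_1"
  expect_true("cross_module_edge" %in% validate_graph(g)$code)
})

test_that("validator reachability agrees with a breadth-first oracle", {
  for (seed in 1:10) {
    g <- random_walk_graph(seed)
    entry <- g$modules[["m1"]]$entry_node
    oracle <- bfs_reachable(g, entry)
    # the generator makes every node reachable; validator must agree
    expect_setequal(oracle, names(g$nodes))
    expect_false("orphan_node" %in% validate_graph(g)$code)
    expect_false("no_reachable_exit" %in% validate_graph(g)$code)
    # detach a node from the chain: oracle and validator must both see it
    g2 <- g
    cut <- names(g2$nodes)[3]
    for (nid in names(g2$nodes)) {
      g2$nodes[[nid]]$out_edges <- lapply(g2$nodes[[nid]]$out_edges, function(e) {
        if (e$target == cut) e$target <- names(g2$nodes)[4]
        e
      })
    }
    oracle2 <- bfs_reachable(g2, entry)
    iss <- validate_graph(g2)
    expect_identical(cut %in% oracle2,
                     !cut %in% iss$location[iss$code == "orphan_node"],
                     label = sprintf("orphan agreement, seed %d", seed))
  }
})

test_that("DOT export mirrors the graph and styles node variants", {
  g <- tiny_graph()
  dot <- to_dot(g)
  expect_identical(length(gregexpr("label=", dot, fixed = TRUE)[[1]]),
                   2L + 1L + 1L) # 2 nodes + 1 edge + 1 cluster
  dot_demo <- to_dot(demo)
  lines <- strsplit(dot_demo, "\n")[[1]]
  n_nodes <- sum(grepl("shape=", lines))
  n_edges <- sum(grepl(" -> ", lines, fixed = TRUE))
  expect_identical(n_nodes, length(demo$nodes))
  expect_identical(n_edges,
                   sum(vapply(demo$nodes, function(nd) length(nd$out_edges), 1L)))
  # branches get a distinct shape
  expect_true(any(grepl('"intro_gate".*shape=diamond', lines)))
})
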