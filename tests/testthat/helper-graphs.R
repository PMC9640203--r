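# Shared fixtures and independent oracles for the suite.

demo <- build_demo_graph()
registry <- default_intents()
lexicon <- default_risk_lexicon()

# smallest legal graph: entry message -> exit
tiny_graph <- function(hint = "end") {
  dialog_graph("tiny", modules = list(
    dialog_module("m1", "Only module", "n1", nodes = list(
      message_node("n1", "hello", to = "x1"),
      exit_module_node("x1", hint = hint)))),
    entry_module = "m1")
}

tiny_yaml <- function() serialize_graph(tiny_graph())

# --- independent breadth-first reachability oracle (queue-based, kept
# deliberately separate from the package's traversal code) ----------------
bfs_reachable <- function(graph, start) {
  queue <- start
  seen <- character(0)
  while (length(queue)) {
    id <- queue[1]
    queue <- queue[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    nd <- graph$nodes[[id]]
    if (is.null(nd)) next
    for (e in nd$out_edges) queue <- c(queue, e$target)
  }
  seen
}

# --- naive recursive reference interpreter -------------------------------
# Walks a single-module graph, choosing quick-reply options via `choose`
# (a function of the node returning a label) and evaluating conditions
# with its own tiny evaluator. Returns the visited-node sequence and the
# inputs it consumed, so the engine can be driven with the same inputs.
naive_interpret <- function(graph, choose) {
  vars <- list()
  pos <- graph$modules[[graph$entry_module]]$entry_node
  visited <- character(0)
  inputs <- list()
  repeat {
    nd <- graph$nodes[[pos]]
    visited <- c(visited, nd$node_id)
    if (nd$type == "exit_module") return(list(visited = visited, inputs = inputs))
    if (nd$type %in% c("message", "rich_media")) {
      pos <- nd$out_edges[[1]]$target
    } else if (nd$type == "update_value") {
      vars[[nd$variable]] <- nd$value
      pos <- nd$out_edges[[1]]$target
    } else if (nd$type == "branch") {
      cc <- nd$condition
      v <- vars[[cc$variable]]
      lbl <- if (is.null(v)) "default"
        else if (switch(cc$operator,
                        eq = v == cc$operand, ne = v != cc$operand,
                        lt = v < cc$operand, le = v <= cc$operand,
                        gt = v > cc$operand, ge = v >= cc$operand,
                        is_set = TRUE)) "true" else "false"
      hit <- Filter(function(e) e$label == lbl, nd$out_edges)
      pos <- hit[[1]]$target
    } else if (nd$type == "quick_replies") {
      lbl <- choose(nd)
      inputs[[length(inputs) + 1L]] <- lbl
      hit <- Filter(function(e) e$label == lbl, nd$out_edges)
      pos <- hit[[1]]$target
    } else stop("naive_interpret: unsupported node type ", nd$type)
  }
}

# --- random graph generators ---------------------------------------------
# DAG over a single module: every node's primary edge goes to the next
# node, extra edges jump forward, the last node exits, so every node is
# reachable and every walk terminates.
random_walk_graph <- function(seed, n_nodes = 10) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- list()
  for (i in seq_len(n_nodes - 1)) {
    nxt <- ids[i + 1]
    fwd <- function() { # guard the length-1 sample() trap
      cand <- seq(i + 1, n_nodes)
      ids[cand[sample.int(length(cand), 1)]]
    }
    type <- sample(c("message", "update", "branch", "quick"), 1,
                   prob = c(.35, .2, .2, .25))
    nodes[[i]] <- switch(type,
      message = message_node(ids[i], paste("msg", i), to = nxt),
      update = update_value_node(ids[i], "x", value = sample(0:5, 1), to = nxt),
      branch = branch_node(ids[i],
                           condition("x", sample(c("eq", "ne", "lt", "ge"), 1),
                                     sample(0:5, 1)),
                           true = nxt, false = fwd(), default = nxt),
      quick = {
        k <- sample(2:3, 1)
        opts <- c(nxt, replicate(k - 1, fwd()))
        names(opts) <- paste0("opt", seq_len(k))
        quick_replies_node(ids[i], paste("q", i), opts)
      })
  }
  nodes[[n_nodes]] <- exit_module_node(ids[n_nodes], hint = "end")
  dialog_graph(paste0("walk", seed),
               modules = list(dialog_module("m1", "Walk", ids[1], nodes)),
               entry_module = "m1")
}

# richer generator exercising every node variant and multiple modules,
# for serialization round-trip tests
random_full_graph <- function(seed) {
  set.seed(seed)
  words <- c("kia ora", "breathe", "it's ok", "tip: rest", "a \"quote\"",
             "emoji \U0001F60A", "x: y", "50% off # not spam")
  txt <- function() paste(sample(words, sample(1:3, 1), TRUE), collapse = " ")
  n_mod <- sample(1:3, 1)
  mods <- list()
  all_entry <- character(0)
  for (m in seq_len(n_mod)) {
    n <- sample(5:9, 1)
    ids <- sprintf("m%d_n%d", m, seq_len(n))
    all_entry <- c(all_entry, ids[1])
    nodes <- list()
    for (i in seq_len(n - 1)) {
      nxt <- ids[i + 1]
      type <- sample(c("message", "quick", "free", "branch", "update",
                       "media", "assess"), 1)
      nodes[[i]] <- switch(type,
        message = message_node(ids[i], replicate(sample(1:3, 1), txt()), to = nxt),
        quick = {
          k <- sample(2:3, 1)
          opts <- rep(nxt, k)
          names(opts) <- paste0("opt ", seq_len(k), " ", sample(words, k))
          quick_replies_node(ids[i], txt(), opts)
        },
        free = free_text_node(ids[i], txt(),
                              intent_edges = c(sadness = nxt, fear = nxt),
                              fallback = nxt),
        branch = branch_node(ids[i], condition("v", "eq", sample(0:9, 1)),
                             true = nxt, false = nxt, default = nxt),
        update = update_value_node(ids[i], "v",
                                   value = if (runif(1) < .5) sample(0:9, 1)
                                           else txt(),
                                   to = nxt),
        media = rich_media_node(ids[i],
                                attachment_ref(sample(c("image", "gif", "audio",
                                                        "video", "webview",
                                                        "poster"), 1),
                                               paste0("a/", i, ".png"),
                                               caption = txt(),
                                               saveable = runif(1) < .5),
                                to = nxt),
        assess = assessment_node(ids[i], txt(), item_id = "worry",
                                 scale_min = 0, scale_max = 10,
                                 anchors = c("lo", "hi"),
                                 required = runif(1) < .5, to = nxt))
    }
    nodes[[n]] <- exit_module_node(ids[n],
                                   hint = if (m < n_mod) paste0("goto:mod", m + 1)
                                          else sample(c("menu", "end"), 1))
    mods[[m]] <- dialog_module(paste0("mod", m), paste("Module", m), ids[1],
                               nodes,
                               role = if (m == 1) "onboarding" else "activity",
                               repeatable = runif(1) < .8,
                               added_post_launch = runif(1) < .3)
  }
  pb <- c(fear = sample(all_entry, 1))
  dialog_graph(paste0("full", seed), mods, entry_module = "mod1",
               priority_bindings = pb,
               metadata = list(title = txt(), version = "1.0"))
}

# drive a session to the first free-text node of the demo pack (the
# feelings question in the introductory-information module)
demo_at_free_text <- function() {
  tr <- start_session(demo, "tester", registry = registry, lexicon = lexicon)
  tr <- advance_turn(tr$session, demo, ui_option("Let's go"),
                     registry = registry, lexicon = lexicon)
  advance_turn(tr$session, demo, ui_score(5),
               registry = registry, lexicon = lexicon)
}

sentinel_text <- "XQZV sentinel utterance that must never be logged"
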