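#' Structural validation of a dialog graph
#'
#' Lints a graph against the authoring-canvas structural rules and returns
#' every finding as data (never an error condition). A graph is clean when
#' the returned table has zero rows. Codes form a closed, documented set:
#'
#' * `missing_entry_module` (error) — `entry_module` names no module.
#' * `missing_module_entry` (error) — a module's `entry_node` does not
#'   exist inside that module.
#' * `unresolved_target` (error) — an edge points to a nonexistent node.
#' * `no_reachable_exit` (error) — no `exit_module` node of the module is
#'   reachable from its entry.
#' * `unrouted_option` (error) — a quick-reply option label without a
#'   matching out-edge (or duplicate labels).
#' * `missing_fallback` (error) — a free-text node without exactly one
#'   fallback edge.
#' * `input_free_cycle` (error) — a cycle through nodes that never await
#'   user input; a turn entering it would not terminate.
#' * `dangling_priority_binding` (error) — a priority digression target
#'   that resolves to no node.
#' * `dangling_exit_hint` (error) — an exit node's `goto:` hint names no
#'   module.
#' * `orphan_node` (warning) — a node unreachable from every module entry
#'   and every priority-binding target.
#' * `branch_missing_default` (warning) — a branch with no `default` edge:
#'   an unset variable at run time would have nowhere to go.
#' * `cross_module_edge` (warning) — an ordinary edge that jumps between
#'   modules; legal, but exits plus menu returns are the cleaner idiom.
#'
#' @param graph a `dialog_graph`.
#' @return a data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `code`, `location` (node or module id) and `message`; zero rows when
#'   the graph is clean.
#' @export
validate_graph <- function(graph) {
  issues <- list()
  add <- function(severity, code, location, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, location = location, message = message)

  nodes <- graph$nodes
  exists_node <- function(id) !is.null(nodes[[id]])

  if (is.null(graph$modules[[graph$entry_module]]))
    add("error", "missing_entry_module", graph$entry_module,
        sprintf("entry_module '%s' is not a module", graph$entry_module))

  for (m in graph$modules) {
    en <- nodes[[m$entry_node]]
    if (is.null(en) || !identical(en$module_id, m$module_id))
      add("error", "missing_module_entry", m$module_id,
          sprintf("entry node '%s' not found in module '%s'",
                  m$entry_node, m$module_id))
  }

  for (nd in nodes) {
    for (e in nd$out_edges)
      if (!exists_node(e$target))
        add("error", "unresolved_target", nd$node_id,
            sprintf("edge '%s' -> unknown node '%s'", e$label, e$target))
    if (nd$type == "quick_replies") {
      labels <- vapply(nd$out_edges, `[[`, "", "label")
      opts <- nd$options %||% labels
      if (anyDuplicated(opts) || !setequal(opts, labels) ||
          length(opts) != length(labels)) {
        missing <- setdiff(opts, labels)
        add("error", "unrouted_option", nd$node_id,
            sprintf("option(s) without a routed edge: %s",
                    paste(if (length(missing)) missing else "(duplicate labels)",
                          collapse = ", ")))
      }
    }
    if (nd$type == "free_text") {
      nfb <- sum(vapply(nd$out_edges, `[[`, "", "label") == "fallback")
      if (nfb != 1L)
        add("error", "missing_fallback", nd$node_id,
            sprintf("free-text node has %d fallback edges (needs exactly 1)", nfb))
    }
    if (nd$type == "branch" &&
        !"default" %in% vapply(nd$out_edges, `[[`, "", "label"))
      add("warning", "branch_missing_default", nd$node_id,
          "branch has no 'default' edge for an unset variable")
    if (nd$type == "exit_module" && startsWith(nd$hint, "goto:")) {
      tgt <- sub("^goto:", "", nd$hint)
      if (is.null(graph$modules[[tgt]]))
        add("error", "dangling_exit_hint", nd$node_id,
            sprintf("exit hint 'goto:%s' names no module", tgt))
    }
    for (e in nd$out_edges)
      if (exists_node(e$target) && nd$type != "exit_module" &&
          !identical(nodes[[e$target]]$module_id, nd$module_id))
        add("warning", "cross_module_edge", nd$node_id,
            sprintf("edge '%s' crosses into module '%s'",
                    e$label, nodes[[e$target]]$module_id))
  }

  for (i in seq_along(graph$priority_bindings))
    if (!exists_node(graph$priority_bindings[[i]]))
      add("error", "dangling_priority_binding",
          names(graph$priority_bindings)[i],
          sprintf("priority intent '%s' bound to unknown node '%s'",
                  names(graph$priority_bindings)[i],
                  graph$priority_bindings[[i]]))

  # per-module reachability of an exit node
  for (m in graph$modules) {
    if (is.null(nodes[[m$entry_node]])) next
    reach <- reachable_from(graph, m$entry_node)
    exits <- vapply(m$nodes, function(nd) nd$type == "exit_module", TRUE)
    exit_ids <- vapply(m$nodes[exits], `[[`, "", "node_id")
    if (!length(exit_ids) || !any(exit_ids %in% reach))
      add("error", "no_reachable_exit", m$module_id,
          "no exit node of this module is reachable from its entry")
  }

  # orphans: unreachable from every module entry and priority target
  roots <- c(vapply(graph$modules, `[[`, "", "entry_node"),
             unlist(graph$priority_bindings))
  roots <- roots[vapply(roots, exists_node, TRUE)]
  reach_all <- unique(unlist(lapply(roots, reachable_from, graph = graph)))
  for (nd in nodes)
    if (!nd$node_id %in% reach_all)
      add("warning", "orphan_node", nd$node_id,
          "node unreachable from every module entry")

  # cycles through input-free nodes would never yield a turn boundary
  auto <- c("message", "branch", "update_value", "rich_media")
  color <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- get0(id, envir = color, ifnotfound = "white")
    if (st == "grey") return(id)
    if (st == "black") return(NULL)
    assign(id, "grey", envir = color)
    nd <- nodes[[id]]
    hit <- NULL
    for (e in nd$out_edges) {
      tn <- nodes[[e$target]]
      if (!is.null(tn) && tn$type %in% auto) {
        hit <- visit(e$target)
        if (!is.null(hit)) break
      }
    }
    assign(id, "black", envir = color)
    hit
  }
  for (nd in nodes) {
    if (!nd$type %in% auto) next
    hit <- visit(nd$node_id)
    if (!is.null(hit)) {
      add("error", "input_free_cycle", hit,
          "cycle with no user-input node: a turn entering it cannot terminate")
      break
    }
  }

  if (!length(issues))
    return(data.frame(severity = character(0), code = character(0),
                      location = character(0), message = character(0)))
  do.call(rbind, issues)
}

# depth-first reachable set over edge targets (exit hints are not edges:
# where control goes after an exit is an engine decision, not graph topology)
reachable_from <- function(graph, start) {
  seen <- character(0)
  stack <- start
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (id %in% seen || is.null(graph$nodes[[id]])) next
    seen <- c(seen, id)
    for (e in graph$nodes[[id]]$out_edges)
      if (!e$target %in% seen) stack <- c(stack, e$target)
  }
  seen
}

DOT_STYLE <- c(
  message      = 'shape=box, style=filled, fillcolor="#fde9c8"',
  quick_replies = 'shape=ellipse, style=filled, fillcolor="#c8e6c9"',
  free_text    = 'shape=ellipse, style=filled, fillcolor="#d1c4e9"',
  branch       = 'shape=diamond, style=filled, fillcolor="#f8bbd0"',
  update_value = 'shape=cds, style=filled, fillcolor="#dcedc8"',
  rich_media   = 'shape=component, style=filled, fillcolor="#b3e5fc"',
  assessment   = 'shape=hexagon, style=filled, fillcolor="#ffe0b2"',
  exit_module  = 'shape=doubleoctagon, style=filled, fillcolor="#fff59d"')

dot_escape <- function(x) gsub('"', '\\\\"', x)

#' Export a dialog graph as Graphviz DOT
#'
#' One DOT node per dialog node (styled by node type — branches render as
#' diamonds, exits as double octagons, ...) and one DOT edge per graph
#' edge with its label preserved. Modules become clusters.
#'
#' @param graph a `dialog_graph`.
#' @return a single string containing a valid DOT `digraph`.
#' @export
to_dot <- function(graph) {
  out <- c(sprintf('digraph "%s" {', dot_escape(graph$graph_id)),
           "  rankdir=LR;")
  for (m in graph$modules) {
    out <- c(out, sprintf('  subgraph "cluster_%s" {', dot_escape(m$module_id)),
             sprintf('    label="%s";', dot_escape(m$title)))
    for (nd in m$nodes)
      out <- c(out, sprintf('    "%s" [label="%s", %s];',
                            dot_escape(nd$node_id),
                            dot_escape(paste0(nd$type, "\\n", nd$node_id)),
                            DOT_STYLE[[nd$type]]))
    out <- c(out, "  }")
  }
  for (nd in graph$nodes)
    for (e in nd$out_edges)
      out <- c(out, sprintf('  "%s" -> "%s" [label="%s"];',
                            dot_escape(nd$node_id), dot_escape(e$target),
                            dot_escape(e$label)))
  out <- c(out, "}")
  paste(out, collapse = "\n")
}
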