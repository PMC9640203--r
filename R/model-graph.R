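#' Create a dialog module
#'
#' A module is a self-contained sub-graph with exactly one entry node and
#' one or more exit nodes, typically teaching one coping skill. The overall
#' dialog is organized as a sequence of modules so that non-technical
#' authors can work on one small piece at a time.
#'
#' @param module_id module identifier (slug, unique within the graph).
#' @param title human-readable title, shown in the module menu.
#' @param entry_node node id of the module's entry point.
#' @param nodes list of nodes created with the `*_node()` constructors.
#' @param role `"onboarding"`, `"activity"` or `"outro"`; only activity
#'   modules appear in the module menu.
#' @param serve_condition optional [condition()]: the module is offered in
#'   the menu only while the condition holds.
#' @param repeatable may the module be re-entered once completed?
#' @param added_post_launch flag for content added after initial release.
#' @return a `dialog_module` object.
#' @export
dialog_module <- function(module_id, title, entry_node, nodes,
                          role = c("activity", "onboarding", "outro"),
                          serve_condition = NULL, repeatable = TRUE,
                          added_post_launch = FALSE) {
  role <- match.arg(role)
  stopifnot(is_scalar_character(module_id), is_scalar_character(entry_node),
            all(vapply(nodes, inherits, logical(1), "dialog_node")))
  if (!is.null(serve_condition)) stopifnot(inherits(serve_condition, "dialog_condition"))
  structure(list(module_id = module_id, title = title, entry_node = entry_node,
                 nodes = nodes, role = role, serve_condition = serve_condition,
                 repeatable = isTRUE(repeatable),
                 added_post_launch = isTRUE(added_post_launch)),
            class = "dialog_module")
}

#' Create a dialog graph
#'
#' The top-level authored artifact: an ordered collection of modules, one
#' global entry module, priority-intent digression targets, and the risk
#' escalation wording. Duplicate module or node identifiers are rejected
#' here; other structural rules (reachability, fallback edges, dangling
#' targets...) are reported by [validate_graph()] so that defective content
#' can still be loaded for linting.
#'
#' @param graph_id graph identifier.
#' @param modules list of [dialog_module()] objects (order is meaningful:
#'   it defines menu order).
#' @param entry_module id of the module where a session starts.
#' @param priority_bindings named character vector, `intent_id = node_id`:
#'   where each priority intent digresses to.
#' @param metadata free-form named list (title, version, locale, ...).
#' @param escalation an [escalation_config()]; defaults to placeholder
#'   wording.
#' @return a `dialog_graph` object.
#' @export
dialog_graph <- function(graph_id, modules, entry_module,
                         priority_bindings = character(0), metadata = list(),
                         escalation = escalation_config()) {
  stopifnot(all(vapply(modules, inherits, logical(1), "dialog_module")))
  mod_ids <- vapply(modules, `[[`, "", "module_id")
  if (anyDuplicated(mod_ids))
    stop_cf("duplicate module identifier: %s", mod_ids[duplicated(mod_ids)][1])
  names(modules) <- mod_ids
  nodes <- list()
  for (m in modules) {
    for (nd in m$nodes) {
      if (!is.null(nodes[[nd$node_id]]))
        stop_cf("duplicate node identifier: %s", nd$node_id)
      nd$module_id <- m$module_id
      nodes[[nd$node_id]] <- nd
    }
  }
  priority_bindings <- unlist(priority_bindings) %||% character(0)
  structure(list(graph_id = graph_id, modules = modules,
                 entry_module = entry_module,
                 priority_bindings = priority_bindings,
                 metadata = metadata, escalation = escalation,
                 nodes = nodes),
            class = "dialog_graph")
}

#' Look up a node by id
#' @param graph a `dialog_graph`.
#' @param node_id node identifier.
#' @return the node, or `NULL` if absent.
#' @export
graph_node <- function(graph, node_id) graph$nodes[[node_id]]

#' @export
print.dialog_graph <- function(x, ...) {
  cat(sprintf("<dialog_graph '%s'> %d modules, %d nodes; entry: %s\n",
              x$graph_id, length(x$modules), length(x$nodes), x$entry_module))
  for (m in x$modules)
    cat(sprintf("  %-28s %-10s %2d nodes%s\n", m$module_id, m$role,
                length(m$nodes), if (m$added_post_launch) "  [post-launch]" else ""))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

cond_to_list <- function(cond) {
  if (is.null(cond)) return(NULL)
  compact(list(variable = cond$variable, operator = cond$operator,
               operand = cond$operand))
}

cond_from_list <- function(x, where) {
  if (is.null(x)) return(NULL)
  if (is.null(x$variable) || is.null(x$operator))
    stop_cf("%s: condition needs variable and operator", where)
  condition(x$variable, x$operator, x$operand)
}

node_to_list <- function(nd) {
  base <- list(id = nd$node_id, type = nd$type)
  single_to <- function() nd$out_edges[[1]]$target
  extra <- switch(nd$type,
    message = list(texts = as.list(nd$texts), to = single_to()),
    quick_replies = list(
      prompt = nd$prompt,
      options = lapply(nd$out_edges,
                       function(e) list(label = e$label, to = e$target))),
    free_text = {
      ie <- Filter(function(e) e$label != "fallback", nd$out_edges)
      fb <- Filter(function(e) e$label == "fallback", nd$out_edges)
      list(prompt = nd$prompt,
           intents = if (length(ie))
             lapply(ie, function(e) list(intent = e$label, to = e$target)),
           fallback = if (length(fb)) fb[[1]]$target)
    },
    branch = {
      tg <- function(lbl) {
        hit <- Filter(function(e) e$label == lbl, nd$out_edges)
        if (length(hit)) hit[[1]]$target
      }
      c(cond_to_list(nd$condition),
        list(when_true = tg("true"), when_false = tg("false"),
             when_default = tg("default")))
    },
    update_value = list(variable = nd$variable, value = nd$value,
                        expr = nd$expr, to = single_to()),
    rich_media = list(
      attachment = compact(list(kind = nd$attachment$kind, ref = nd$attachment$ref,
                                caption = nd$attachment$caption,
                                saveable = nd$attachment$saveable)),
      to = single_to()),
    assessment = list(prompt = nd$prompt, item = nd$item_id,
                      scale = list(nd$scale_min, nd$scale_max),
                      anchors = as.list(nd$anchors), required = nd$required,
                      to = single_to()),
    exit_module = list(hint = nd$hint))
  compact(c(base, extra))
}

node_from_list <- function(nl) {
  id <- nl$id
  if (is.null(id) || is.null(nl$type))
    stop_cf("node entry missing 'id' or 'type' (near id '%s')", id %||% "?")
  if (!nl$type %in% NODE_TYPES)
    stop_cf("unknown node type '%s' at node '%s'", nl$type, id)
  switch(nl$type,
    message = message_node(id, unlist(nl$texts), nl$to),
    quick_replies = {
      opts <- vapply(nl$options, function(o) o$to, "")
      names(opts) <- vapply(nl$options, function(o) as.character(o$label), "")
      quick_replies_node(id, nl$prompt, opts)
    },
    free_text = {
      ie <- NULL
      if (length(nl$intents)) {
        ie <- vapply(nl$intents, function(o) o$to, "")
        names(ie) <- vapply(nl$intents, function(o) o$intent, "")
      }
      if (is.null(nl$fallback))
        stop_cf("free_text node '%s' has no fallback edge", id)
      free_text_node(id, nl$prompt, ie, nl$fallback)
    },
    branch = branch_node(id, condition(nl$variable, nl$operator, nl$operand),
                         true = nl$when_true, false = nl$when_false,
                         default = nl$when_default),
    update_value = update_value_node(id, nl$variable, value = nl$value,
                                     expr = nl$expr, to = nl$to),
    rich_media = rich_media_node(
      id, attachment_ref(nl$attachment$kind, nl$attachment$ref,
                         nl$attachment$caption,
                         isTRUE(nl$attachment$saveable)), nl$to),
    assessment = assessment_node(id, nl$prompt, nl$item,
                                 scale_min = nl$scale[[1]], scale_max = nl$scale[[2]],
                                 anchors = unlist(nl$anchors),
                                 required = nl$required %||% TRUE, to = nl$to),
    exit_module = exit_module_node(id, nl$hint %||% "menu"))
}

module_to_list <- function(m) {
  compact(list(
    module_id = m$module_id, title = m$title, role = m$role,
    entry_node = m$entry_node,
    serve_condition = cond_to_list(m$serve_condition),
    repeatable = if (!m$repeatable) FALSE,
    added_post_launch = if (m$added_post_launch) TRUE,
    nodes = lapply(m$nodes, node_to_list)))
}

module_from_list <- function(ml) {
  dialog_module(ml$module_id, ml$title, ml$entry_node,
                nodes = lapply(ml$nodes, node_from_list),
                role = ml$role %||% "activity",
                serve_condition = cond_from_list(ml$serve_condition,
                                                 ml$module_id %||% "?"),
                repeatable = ml$repeatable %||% TRUE,
                added_post_launch = ml$added_post_launch %||% FALSE)
}

#' Serialize a dialog graph to canonical YAML
#'
#' The output is canonical: mapping keys are emitted in sorted order (node
#' and option sequences keep their meaningful order), so serializing the
#' same graph twice yields byte-identical text and
#' `parse_graph(serialize_graph(g))` is structurally identical to `g`.
#'
#' @param graph a `dialog_graph`.
#' @return a single YAML string.
#' @seealso [parse_graph()], [write_graph()]
#' @export
serialize_graph <- function(graph) {
  doc <- compact(list(
    graph_id = graph$graph_id,
    entry_module = graph$entry_module,
    metadata = if (length(graph$metadata)) graph$metadata,
    priority_bindings = if (length(graph$priority_bindings))
      as.list(graph$priority_bindings),
    escalation = unclass(graph$escalation),
    modules = lapply(unname(graph$modules), module_to_list)))
  yaml::as.yaml(sort_keys(doc), indent.mapping.sequence = TRUE)
}

#' Write a dialog graph to a YAML content-pack file
#' @inheritParams serialize_graph
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  writeLines(serialize_graph(graph), path, useBytes = TRUE)
  invisible(path)
}

#' Parse a dialog graph from a YAML content pack
#'
#' Reads the graph, builds typed nodes, and resolves every reference: the
#' entry module and each module's entry node must exist, every edge target
#' and every priority-binding target must name an existing node. Unresolved
#' references are errors — a partially resolved graph is never returned.
#' Structural linting beyond reference resolution (reachability, missing
#' fallbacks, ...) is the job of [validate_graph()].
#'
#' @param x path to a `.yaml` file, or a YAML string (anything containing a
#'   newline is treated as text).
#' @return a `dialog_graph`.
#' @export
parse_graph <- function(x) {
  looks_like_yaml <- grepl("\n", x[1], fixed = TRUE) || grepl(":", x[1], fixed = TRUE)
  txt <- if (is_scalar_character(x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else if (looks_like_yaml) {
    paste(x, collapse = "\n")
  } else stop_cf("content pack not found: %s", x)
  doc <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) stop_cf("YAML syntax error: %s", conditionMessage(e)))
  if (is.null(doc$graph_id) || is.null(doc$modules) || is.null(doc$entry_module))
    stop_cf("content pack must define graph_id, entry_module and modules")
  esc <- if (!is.null(doc$escalation)) do.call(escalation_config, doc$escalation)
         else escalation_config()
  g <- dialog_graph(doc$graph_id,
                    modules = lapply(doc$modules, module_from_list),
                    entry_module = doc$entry_module,
                    priority_bindings = unlist(doc$priority_bindings) %||% character(0),
                    metadata = doc$metadata %||% list(),
                    escalation = esc)
  assert_references(g)
  g
}

assert_references <- function(g) {
  if (is.null(g$modules[[g$entry_module]]))
    stop_cf("unresolved reference: entry_module '%s' is not a module", g$entry_module)
  for (m in g$modules) {
    en <- g$nodes[[m$entry_node]]
    if (is.null(en) || en$module_id != m$module_id)
      stop_cf("unresolved reference: entry node '%s' of module '%s'",
              m$entry_node, m$module_id)
  }
  for (nd in g$nodes) {
    for (e in nd$out_edges) {
      if (is.null(g$nodes[[e$target]]))
        stop_cf("unresolved edge target '%s' (edge '%s' from node '%s')",
                e$target, e$label, nd$node_id)
    }
    if (nd$type == "exit_module" && startsWith(nd$hint, "goto:")) {
      tgt <- sub("^goto:", "", nd$hint)
      if (is.null(g$modules[[tgt]]))
        stop_cf("unresolved exit hint 'goto:%s' at node '%s'", tgt, nd$node_id)
    }
  }
  for (i in seq_along(g$priority_bindings)) {
    tgt <- g$priority_bindings[[i]]
    if (is.null(g$nodes[[tgt]]))
      stop_cf("unresolved priority binding: intent '%s' -> node '%s'",
              names(g$priority_bindings)[i], tgt)
  }
  invisible(g)
}

#' Structural equality of two dialog graphs
#'
#' Graphs are compared through their canonical serializations, so ordering
#' of mapping keys and internal indexes are irrelevant.
#'
#' @param a,b `dialog_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(a, b) identical(serialize_graph(a), serialize_graph(b))
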