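#' @title Dialog node constructors
#'
#' @description A dialog graph is made of typed vertices ("nodes") joined by
#' labeled edges. Some node types emit output when visited (messages, rich
#' media), some request user input (quick replies, free text, assessments),
#' and some are invisible control flow (branches, value updates). Every node
#' has a graph-unique `node_id` and a list of out-edges; the constructors
#' below enforce the per-type arity rules (e.g. a message node has exactly
#' one out-edge, a free-text node has exactly one fallback edge).
#'
#' @name dialog-nodes
NULL

NODE_TYPES <- c("message", "quick_replies", "free_text", "branch",
                "update_value", "rich_media", "assessment", "exit_module")

CONDITION_OPERATORS <- c("eq", "ne", "lt", "le", "gt", "ge", "is_set")

ATTACHMENT_KINDS <- c("image", "gif", "audio", "video", "webview", "poster")

#' Create a labeled edge to another node
#'
#' @param target node id the edge points to (may live in another module).
#' @param label edge label: a quick-reply option text, an intent id, a
#'   branch outcome (`"true"`, `"false"`, `"default"`), or `"default"`.
#' @return a `dialog_edge` object.
#' @export
edge <- function(target, label = "default") {
  stopifnot(is_scalar_character(target), is_scalar_character(label))
  structure(list(target = target, label = label), class = "dialog_edge")
}

#' Create a condition over a session variable
#'
#' Conditions gate branches and module serving. Variables are simple typed
#' scalars (integer, logical or short string); the operator set is closed.
#'
#' @param variable variable name.
#' @param operator one of `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `is_set`.
#' @param operand literal to compare against (ignored for `is_set`).
#' @return a `dialog_condition` object.
#' @export
condition <- function(variable, operator, operand = NULL) {
  operator <- match.arg(operator, CONDITION_OPERATORS)
  if (operator != "is_set" && is.null(operand))
    stop_cf("condition: operator '%s' requires an operand", operator)
  structure(list(variable = variable, operator = operator, operand = operand),
            class = "dialog_condition")
}

#' Create a reference to a media attachment
#'
#' Attachments are opaque references (a path or URI) with a kind drawn from
#' a closed set; `poster` denotes styled tip-sheet images users may save
#' for later review, `webview` an in-channel web page.
#'
#' @param kind one of image, gif, audio, video, webview, poster.
#' @param ref path or URI of the asset.
#' @param caption optional caption text.
#' @param saveable may the user save this item for later sessions?
#' @return an `attachment_ref` object.
#' @export
attachment_ref <- function(kind, ref, caption = NULL, saveable = FALSE) {
  kind <- match.arg(kind, ATTACHMENT_KINDS)
  structure(list(kind = kind, ref = ref, caption = caption,
                 saveable = isTRUE(saveable)),
            class = "attachment_ref")
}

new_node <- function(node_id, type, out_edges, fields = list()) {
  stopifnot(is_scalar_character(node_id))
  type <- match.arg(type, NODE_TYPES)
  stopifnot(all(vapply(out_edges, inherits, logical(1), "dialog_edge")))
  structure(c(list(node_id = node_id, type = type, module_id = NA_character_,
                   out_edges = out_edges), fields),
            class = "dialog_node")
}

#' @describeIn dialog-nodes one or more consecutive text bubbles, then a
#'   single unlabeled transition. Splitting longer passages across 2-3
#'   bubbles is the idiomatic way to pace content.
#' @param node_id graph-unique node identifier (slug, case-sensitive).
#' @param texts character vector of message texts (each sent as its own bubble).
#' @param to target node id of the single out-edge.
#' @export
message_node <- function(node_id, texts, to) {
  stopifnot(is.character(texts), length(texts) >= 1)
  new_node(node_id, "message", list(edge(to)), list(texts = as.character(texts)))
}

#' @describeIn dialog-nodes a prompt plus a closed set of tappable options;
#'   each option label maps to exactly one out-edge.
#' @param prompt prompt text shown with the options.
#' @param options named character vector or list: `label = target_node_id`.
#' @export
quick_replies_node <- function(node_id, prompt, options) {
  options <- unlist(options)
  if (is.null(names(options)) || any(!nzchar(names(options))))
    stop_cf("quick_replies_node '%s': options must be named label = target", node_id)
  edges <- lapply(seq_along(options),
                  function(i) edge(options[[i]], names(options)[i]))
  new_node(node_id, "quick_replies", edges,
           list(prompt = prompt, options = names(options)))
}

#' @describeIn dialog-nodes free-text input; the classified intent selects a
#'   locally configured intent edge, anything unmapped takes the single
#'   mandatory fallback edge. Many intents may converge on one target.
#' @param intent_edges named vector/list: `intent_id = target_node_id`.
#' @param fallback target node id of the fallback edge.
#' @export
free_text_node <- function(node_id, prompt, intent_edges = NULL, fallback) {
  intent_edges <- unlist(intent_edges)
  edges <- lapply(seq_along(intent_edges),
                  function(i) edge(intent_edges[[i]], names(intent_edges)[i]))
  edges <- c(edges, list(edge(fallback, "fallback")))
  new_node(node_id, "free_text", edges, list(prompt = prompt))
}

#' @describeIn dialog-nodes invisible two/three-way switch on a condition;
#'   out-edges labeled `"true"`, `"false"` and optionally `"default"` (taken
#'   when the condition's variable is unset).
#' @param cond a [condition()].
#' @param true target when the condition holds.
#' @param false target when it does not.
#' @param default target when the variable is unset (falls back to `false`'s
#'   edge only if explicitly given; the validator warns when absent).
#' @export
branch_node <- function(node_id, cond, true, false, default = NULL) {
  stopifnot(inherits(cond, "dialog_condition"))
  edges <- list(edge(true, "true"), edge(false, "false"))
  if (!is.null(default)) edges <- c(edges, list(edge(default, "default")))
  new_node(node_id, "branch", edges, list(condition = cond))
}

#' @describeIn dialog-nodes invisible variable assignment. `value` is a
#'   literal; alternatively `expr` is a simple arithmetic expression of the
#'   form `"var"`, `"var + k"` or `"var - k"` over an existing variable.
#' @param variable variable name to set.
#' @param value literal value (integer, logical, or short string).
#' @param expr simple expression string, mutually exclusive with `value`.
#' @export
update_value_node <- function(node_id, variable, value = NULL, expr = NULL, to) {
  if (is.null(value) == is.null(expr))
    stop_cf("update_value_node '%s': give exactly one of value/expr", node_id)
  new_node(node_id, "update_value", list(edge(to)),
           list(variable = variable, value = value, expr = expr))
}

#' @describeIn dialog-nodes emits an attachment (image, GIF, poster, ...)
#'   then transitions on its single out-edge.
#' @param attachment an [attachment_ref()].
#' @export
rich_media_node <- function(node_id, attachment, to) {
  stopifnot(inherits(attachment, "attachment_ref"))
  new_node(node_id, "rich_media", list(edge(to)), list(attachment = attachment))
}

#' @describeIn dialog-nodes administers a single-item self-report scale
#'   (the shipped content uses a 0-10 worry item anchored "no worries" /
#'   "totally freaking out"). When `required` is `FALSE` the user may
#'   decline, which records nothing.
#' @param item_id assessment item identifier.
#' @param scale_min,scale_max integer scale bounds.
#' @param anchors length-2 character vector: labels of the two scale ends.
#' @param required if `FALSE`, a decline input skips the item.
#' @export
assessment_node <- function(node_id, prompt, item_id, scale_min = 0L,
                            scale_max = 10L, anchors = c("low", "high"),
                            required = TRUE, to) {
  stopifnot(scale_min < scale_max, length(anchors) == 2)
  new_node(node_id, "assessment", list(edge(to)),
           list(prompt = prompt, item_id = item_id,
                scale_min = as.integer(scale_min),
                scale_max = as.integer(scale_max),
                anchors = as.character(anchors), required = isTRUE(required)))
}

#' @describeIn dialog-nodes terminal vertex of a module. The `hint` tells
#'   the engine where control goes next: `"menu"` re-offers the module menu,
#'   `"end"` routes into session wrap-up, `"goto:<module_id>"` chains
#'   straight into another module's entry.
#' @param hint next-step hint (default `"menu"`).
#' @export
exit_module_node <- function(node_id, hint = "menu") {
  stopifnot(is_scalar_character(hint))
  if (!hint %in% c("menu", "end") && !startsWith(hint, "goto:"))
    stop_cf("exit_module_node '%s': hint must be 'menu', 'end' or 'goto:<module>'", node_id)
  new_node(node_id, "exit_module", list(), list(hint = hint))
}

#' @export
print.dialog_node <- function(x, ...) {
  lbls <- vapply(x$out_edges, function(e) sprintf("%s->%s", e$label, e$target), "")
  cat(sprintf("<%s node '%s'%s> edges: %s\n", x$type, x$node_id,
              if (is.na(x$module_id)) "" else paste0(" @", x$module_id),
              if (length(lbls)) paste(lbls, collapse = ", ") else "(terminal)"))
  invisible(x)
}
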