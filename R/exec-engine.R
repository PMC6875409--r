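# Execution engine: collect form values into bindings, build the execution
# network, evaluate it with token semantics and assemble command invocations.
#
# Evaluation follows petri-net token semantics: every node is a place, its
# function the transition; a transition needs tokens (values) on all of its
# input places before it produces its own token. Because the graph is
# acyclic and evaluation is pure, this is realised as demand-driven
# memoized evaluation — each place holds at most one token per assembly.

#' Collect user input values into bindings
#'
#' Walks the window model in document order and produces the total binding
#' map the engine assembles from. Booleans (check boxes and checkable group
#' boxes) are rendered as the strings `"TRUE"`/`"FALSE"`; file-dialog values
#' are flagged path-typed; everything else passes through verbatim. Defaults
#' fill missing values; a missing value with no default is an error naming
#' the element.
#'
#' @param window list of window elements (the `window` field of a template),
#'   or a `forge_template` (its window model is used).
#' @param raw named list/vector of raw values (character or logical).
#' @return A `forge_bindings` object: `values` (named character list),
#'   `path_typed` and `secret` (character vectors of ids).
#' @export
collect_bindings <- function(window, raw = list()) {
  if (inherits(window, "forge_template")) window <- window$window
  raw <- as.list(raw)
  values <- list()
  path_typed <- character(0)
  secret <- character(0)
  for (el in window_elements_flat(window)) {
    if (is.null(el$id)) next
    boolean <- el$kind == "checkbox" ||
      (el$kind == "group" && isTRUE(el$checkable))
    bindable <- el$kind %in% BINDABLE_KINDS || boolean
    if (!bindable) next
    v <- raw[[el$id]]
    if (is.null(v)) v <- el$default
    if (is.null(v) && boolean) v <- "FALSE"
    if (is.null(v) && el$kind == "combobox" && length(el$options))
      v <- el$options[[1]]
    if (is.null(v))
      stop(sprintf("no value and no default for element '%s'", el$id),
           call. = FALSE)
    if (boolean) {
      v <- render_boolean(v, el$id)
    } else {
      v <- as.character(v)
    }
    if (el$kind == "combobox" && !v %in% unlist(el$options))
      stop(sprintf("value '%s' for combobox '%s' is not among its options",
                   v, el$id), call. = FALSE)
    values[[el$id]] <- v
    if (el$kind == "filedialog") path_typed <- c(path_typed, el$id)
    if (isTRUE(el$secret)) secret <- c(secret, el$id)
  }
  structure(list(values = values, path_typed = path_typed, secret = secret),
            class = "forge_bindings")
}

render_boolean <- function(v, id) {
  if (is.logical(v)) return(if (isTRUE(v)) "TRUE" else "FALSE")
  vv <- toupper(as.character(v))
  if (!vv %in% c("TRUE", "FALSE"))
    stop(sprintf("element '%s' expects TRUE/FALSE, got '%s'", id, v),
         call. = FALSE)
  vv
}

#' @export
print.forge_bindings <- function(x, ...) {
  cat(sprintf("<bindings> %d values\n", length(x$values)))
  for (id in names(x$values)) {
    v <- if (id %in% x$secret) "<secret>" else x$values[[id]]
    flags <- c(if (id %in% x$path_typed) "path",
               if (id %in% x$secret) "secret")
    cat(sprintf("  %s = %s%s\n", id, v,
                if (length(flags)) paste0(" [", paste(flags, collapse = ","),
                                          "]") else ""))
  }
  invisible(x)
}

#' Substitute `${id}` references in text
#'
#' Every `${id}` is replaced by the binding value or the referenced node's
#' evaluated token; `$$` yields a literal `$`. Unterminated `${` or an
#' unresolvable id is an error.
#'
#' @param text character scalar.
#' @param ctx an evaluation context from [eval_context()], or a plain named
#'   list/character vector used as a value map.
#' @return character scalar with all references resolved.
#' @export
substitute_refs <- function(text, ctx) {
  if (!inherits(ctx, "forge_eval_ctx")) {
    vals <- as.list(ctx)
    ctx <- structure(list(lookup = function(id) {
      if (!id %in% names(vals))
        stop(sprintf("unresolved reference '${%s}'", id), call. = FALSE)
      as.character(vals[[id]])
    }), class = "forge_eval_ctx")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "$" && i < n && chars[i + 1L] == "$") {
      out <- c(out, "$")
      i <- i + 2L
    } else if (ch == "$" && i < n && chars[i + 1L] == "{") {
      j <- i + 2L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n)
        stop("unterminated ${ reference in: ", text, call. = FALSE)
      ident <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
      if (!grepl(IDENT_RE, ident))
        stop("invalid reference identifier '", ident, "'", call. = FALSE)
      out <- c(out, ctx$lookup(ident))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# ---- execution network -----------------------------------------------------

#' Build the execution network
#'
#' One place and one transition per node; additionally one place per window
#' element referenced from the model. A node referenced by several parents
#' is still a single place (single evaluation). Acyclicity is re-checked.
#'
#' @param exec_model list of execution nodes (the `execution` field of a
#'   template), or a `forge_template`.
#' @return A `forge_network`: `nodes` (named list, anonymous inline nodes
#'   get generated non-referenceable ids), `edges` (named list id ->
#'   referenced ids, i.e. input places), `element_places` (referenced window
#'   ids), `sinks` (execute node ids in document order), `order` (all node
#'   ids in document order).
#' @export
build_network <- function(exec_model) {
  if (inherits(exec_model, "forge_template")) exec_model <- exec_model$execution
  nodes <- list()
  edges <- list()
  order <- character(0)
  sinks <- character(0)
  anon_counter <- new.env(parent = emptyenv())
  anon_counter$n <- 0L

  register <- function(node) {
    id <- node$id
    if (is.null(id)) {
      anon_counter$n <- anon_counter$n + 1L
      id <- sprintf(".anon%d", anon_counter$n)
      node$id <- id
    }
    nodes[[id]] <<- node
    order <<- c(order, id)
    # inline children are registered as their own places
    inline <- inline_children(node)
    inline_ids <- vapply(inline, function(ch) register(ch), character(1))
    edges[[id]] <<- c(direct_text_refs(node), inline_ids)
    if (node$kind == "execute") sinks <<- c(sinks, id)
    id
  }
  for (node in exec_model) register(node)

  node_ids <- names(nodes)
  element_places <- setdiff(unique(unlist(edges)), node_ids)

  # acyclicity re-check over node->node edges
  colour <- new.env(parent = emptyenv())
  visit <- function(id) {
    state <- get0(id, envir = colour, ifnotfound = "white")
    if (state == "grey")
      stop(sprintf("cycle in execution graph involving '%s'", id),
           call. = FALSE)
    if (state == "black") return(invisible())
    assign(id, "grey", envir = colour)
    for (dep in intersect(edges[[id]] %||% character(0), node_ids))
      visit(dep)
    assign(id, "black", envir = colour)
  }
  for (id in node_ids) visit(id)

  structure(list(nodes = nodes, edges = edges,
                 element_places = element_places,
                 sinks = sinks, order = order),
            class = "forge_network")
}

# inline (anonymous) child nodes of a node, in evaluation order
inline_children <- function(node) {
  from_frag <- function(parts)
    lapply(Filter(function(p) p$type == "node", parts), function(p) p$node)
  switch(node$kind,
    add = from_frag(node$parts),
    "if" = c(from_frag(node$then),
             if (!is.null(node$else_)) from_frag(node$else_)),
    execute = {
      out <- list()
      for (p in node$params) out <- c(out, from_frag(p$fragment))
      out
    },
    list())
}

# ${refs} appearing in the node's own text (not via inline children)
direct_text_refs <- function(node) {
  from_frag <- function(parts)
    unlist(lapply(Filter(function(p) p$type == "text", parts),
                  function(p) scan_refs(p$text))) %||% character(0)
  switch(node$kind,
    const = character(0),
    env = character(0),
    add = from_frag(node$parts),
    "if" = unique(c(scan_refs(node$probe), from_frag(node$then),
                    if (!is.null(node$else_)) from_frag(node$else_))),
    script = unlist(lapply(node$argv, scan_refs)) %||% character(0),
    execute = {
      out <- scan_refs(node$program)
      for (p in node$params) out <- c(out, from_frag(p$fragment))
      unique(out)
    })
}

#' @export
print.forge_network <- function(x, ...) {
  cat(sprintf("<execution network> %d places (%d window), %d execute sink(s)\n",
              length(x$nodes) + length(x$element_places),
              length(x$element_places), length(x$sinks)))
  invisible(x)
}

# ---- evaluation ------------------------------------------------------------

#' Create an evaluation context
#'
#' Bundles bindings, the network and the injected environment into the
#' context [evaluate_node()] and [substitute_refs()] operate on. When `env`
#' is `NULL`, `<env>` nodes read the live process environment; supplying a
#' named list makes evaluation fully hermetic (used by tests and saved-run
#' reproduction).
#'
#' @param network a `forge_network`.
#' @param bindings a `forge_bindings`.
#' @param env named list injected environment, or `NULL` for live lookup.
#' @param memoize evaluate each node at most once per assembly (token
#'   semantics). `FALSE` re-evaluates per reference (the naive oracle).
#' @return A `forge_eval_ctx`.
#' @export
eval_context <- function(network, bindings, env = NULL, memoize = TRUE) {
  memo <- new.env(parent = emptyenv())
  fired <- new.env(parent = emptyenv())
  ctx <- new.env(parent = emptyenv())
  ctx$network <- network
  ctx$bindings <- bindings
  ctx$env <- env
  ctx$memoize <- memoize
  ctx$memo <- memo
  ctx$fired <- fired
  ctx$lookup <- function(id) {
    if (id %in% names(bindings$values)) return(bindings$values[[id]])
    if (id %in% names(network$nodes)) return(evaluate_node(id, ctx))
    stop(sprintf("unresolved reference '${%s}'", id), call. = FALSE)
  }
  class(ctx) <- "forge_eval_ctx"
  ctx
}

#' Evaluate one node of the execution network
#'
#' Demand-driven token evaluation: the node's transition fires once all of
#' its input places carry values (resolved recursively), producing its
#' token. With memoization on, each node fires at most once per assembly;
#' `ctx$fired` counts transition firings for instrumentation.
#'
#' Node semantics: `const` yields its literal; `add` concatenates its parts
#' in order, joined by `sep`; `env` looks the key up in the injected (or
#' live) environment; `if` compares the substituted probe text with `equals`
#' (exact, case-sensitive) and yields the then- or else-token (empty text
#' when the else branch is absent); `script` delegates to the script host;
#' `execute` yields its fully assembled argument text.
#'
#' @param node_id id of the node (or an inline-generated id).
#' @param ctx a `forge_eval_ctx`.
#' @return character scalar: the node's token.
#' @export
evaluate_node <- function(node_id, ctx) {
  if (ctx$memoize && !is.null(ctx$memo[[node_id]]))
    return(ctx$memo[[node_id]])
  node <- ctx$network$nodes[[node_id]]
  if (is.null(node))
    stop(sprintf("unknown node '%s'", node_id), call. = FALSE)
  ctx$fired[[node_id]] <- (ctx$fired[[node_id]] %||% 0L) + 1L
  val <- eval_node_value(node, ctx)
  if (ctx$memoize) ctx$memo[[node_id]] <- val
  val
}

# transition function of a node; shared by registry lookup and by inline
# (anonymous, single-reference) nodes evaluated in place
eval_node_value <- function(node, ctx) {
  switch(node$kind,
    const = node$value,
    add = {
      parts <- vapply(node$parts, function(p) eval_part(p, ctx), character(1))
      paste(parts, collapse = node$sep)
    },
    env = lookup_env(node$key, ctx),
    "if" = {
      probe_val <- substitute_refs(node$probe, ctx)
      if (identical(probe_val, node$equals)) eval_fragment(node$then, ctx)
      else if (!is.null(node$else_)) eval_fragment(node$else_, ctx)
      else ""
    },
    script = {
      args <- vapply(node$argv, function(a) substitute_refs(a, ctx),
                     character(1))
      evaluate_script(node, args)
    },
    execute = assemble_execute(node, ctx)$argument_text,
    stop("unknown node kind: ", node$kind)
  )
}

eval_part <- function(p, ctx) {
  if (p$type == "text") return(substitute_refs(p$text, ctx))
  if (is.null(p$node$id)) eval_node_value(p$node, ctx)
  else evaluate_node(p$node$id, ctx)
}

eval_fragment <- function(parts, ctx) {
  paste(vapply(parts, function(p) eval_part(p, ctx), character(1)),
        collapse = "")
}

lookup_env <- function(key, ctx) {
  if (!is.null(ctx$env)) {
    if (!key %in% names(ctx$env))
      stop(sprintf("env node: unknown key '%s' in injected environment", key),
           call. = FALSE)
    return(as.character(ctx$env[[key]]))
  }
  v <- Sys.getenv(key, unset = NA)
  if (is.na(v))
    stop(sprintf("env node: environment variable '%s' is not set", key),
         call. = FALSE)
  v
}

# assemble one execute node: params evaluated in order; a param that
# evaluates to empty text is omitted (conditional flags leave no trace);
# quote="shell" wraps the value in double quotes, escaping embedded quotes
assemble_execute <- function(node, ctx) {
  params <- character(0)
  for (p in node$params) {
    v <- eval_fragment(p$fragment, ctx)
    if (identical(p$quote, "shell"))
      v <- paste0("\"", gsub("\"", "\\\\\"", v), "\"")
    if (nzchar(v)) params <- c(params, v)
  }
  list(program = substitute_refs(node$program, ctx),
       argument_text = paste(params, collapse = " "))
}

# ---- invocation assembly ---------------------------------------------------

new_invocation <- function(program, argument_text, backend = backend_native(),
                           bindings = NULL, template_id = NULL, argv = NULL,
                           secret_slots = integer(0)) {
  structure(list(program = program, argument_text = argument_text,
                 backend = backend, bindings = bindings,
                 template_id = template_id, argv = argv,
                 secret_slots = secret_slots, capture = "lines"),
            class = "forge_invocation")
}

#' @export
print.forge_invocation <- function(x, ...) {
  cat(sprintf("<invocation> %s %s\n", x$program, invocation_display(x)))
  cat(sprintf("  backend: %s\n", x$backend$kind))
  invisible(x)
}

# display form with secret positional slots masked
invocation_display <- function(x) {
  if (is.null(x$argv)) return(x$argument_text)
  shown <- x$argv
  if (length(x$secret_slots))
    shown[x$secret_slots] <- "***"
  paste(shown, collapse = " ")
}

#' Assemble command invocations from a template and bindings
#'
#' The engine's sole output before execution: one invocation per execute
#' node in document order, fully resolved argument text, no process started
#' and no filesystem touched. Identical (template, bindings, environment)
#' always yield identical invocations.
#'
#' @param t a valid `forge_template`.
#' @param bindings a `forge_bindings` (total for the template) or a raw
#'   value map passed through [collect_bindings()].
#' @param env injected environment (named list) or `NULL` for live lookup.
#' @return list of `forge_invocation`.
#' @export
assemble_invocation <- function(t, bindings, env = NULL) {
  stopifnot(inherits(t, "forge_template"))
  if (!inherits(bindings, "forge_bindings"))
    bindings <- collect_bindings(t$window, bindings)
  network <- build_network(t$execution)
  ctx <- eval_context(network, bindings, env = env)
  out <- list()
  for (id in network$sinks) {
    node <- network$nodes[[id]]
    asm <- assemble_execute(node, ctx)
    out[[length(out) + 1L]] <- new_invocation(
      program = asm$program, argument_text = asm$argument_text,
      bindings = bindings, template_id = t$id)
  }
  out
}
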