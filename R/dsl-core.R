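# Template DSL: domain types, XML parsing/serialization, validation and the
# neutral form-schema export.
#
# A template document has two parts under a <template> root:
#   <window>    -- the form tree: label, input, checkbox, filedialog,
#                  combobox, group, action, streambox
#   <execution> -- the dataflow nodes: const, add, env, if, script, execute
# Text anywhere in execution nodes may reference window elements or other
# nodes as ${id}; `$$` escapes a literal dollar sign.

WINDOW_TAGS <- c("label", "input", "checkbox", "filedialog", "combobox",
                 "group", "action", "streambox")
EXEC_TAGS <- c("const", "add", "env", "if", "script", "execute")
# element kinds whose value can be referenced from the execution model
BINDABLE_KINDS <- c("input", "checkbox", "filedialog", "combobox")

IDENT_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Create a diagnostic record
#'
#' Diagnostics are the currency of [validate_template()]: plain records with
#' a severity, the id (or document position) of the offender and a message.
#'
#' @param severity `"error"` or `"warning"`.
#' @param location element/node id or a document position string.
#' @param message human-readable description.
#' @return A `forge_diagnostic` object.
#' @export
diagnostic <- function(severity, location, message) {
  stopifnot(severity %in% c("error", "warning"))
  structure(list(severity = severity, location = location, message = message),
            class = "forge_diagnostic")
}

#' @export
print.forge_diagnostic <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", x$severity, x$location, x$message))
  invisible(x)
}

#' @export
format.forge_diagnostic <- function(x, ...) {
  sprintf("[%s] %s: %s", x$severity, x$location, x$message)
}

new_window_element <- function(kind, id = NULL, label = NULL, hint = NULL,
                               default = NULL, mode = NULL, options = NULL,
                               title = NULL, checkable = FALSE,
                               layout = NULL, secret = FALSE,
                               children = NULL) {
  structure(list(kind = kind, id = id, label = label, hint = hint,
                 default = default, mode = mode, options = options,
                 title = title, checkable = checkable, layout = layout,
                 secret = secret, children = children),
            class = "forge_window_element")
}

new_exec_node <- function(kind, id = NULL, ...) {
  structure(c(list(kind = kind, id = id), list(...)), class = "forge_exec_node")
}

# A fragment is an ordered list of parts, each either
#   list(type = "text", text = <chr>)            -- may contain ${refs}
#   list(type = "node", node = <forge_exec_node>) -- inline anonymous node
frag_text <- function(text) list(type = "text", text = text)
frag_node <- function(node) list(type = "node", node = node)

new_template <- function(id, title, description, window, execution) {
  structure(list(id = id, title = title, description = description,
                 window = window, execution = execution),
            class = "forge_template")
}

#' @export
print.forge_template <- function(x, ...) {
  n_widgets <- length(window_elements_flat(x$window))
  cat(sprintf("<template> %s: \"%s\"\n", x$id, x$title))
  if (nzchar(x$description %||% ""))
    cat(" ", x$description, "\n")
  cat(sprintf("  window: %d elements (%d bindable)\n", n_widgets,
              length(bindable_ids(x$window))))
  cat(sprintf("  execution: %d nodes (%d execute)\n", length(x$execution),
              sum(vapply(x$execution, function(n) n$kind == "execute",
                         logical(1)))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

known_attrs <- list(
  template  = c("id", "title", "description"),
  label     = character(0),
  input     = c("id", "label", "default", "hint", "secret"),
  checkbox  = c("id", "label", "default", "hint"),
  filedialog = c("id", "label", "mode", "default", "hint"),
  combobox  = c("id", "label", "default", "hint"),
  group     = c("id", "title", "checkable", "layout"),
  action    = c("label"),
  streambox = c("id"),
  option    = character(0),
  const     = c("id", "value"),
  add       = c("id", "sep"),
  env       = c("id", "key"),
  "if"      = c("id", "probe", "equals"),
  script    = c("id", "argv", "dialect"),
  execute   = c("id", "program"),
  param     = c("quote"),
  then      = character(0),
  "else"    = character(0)
)

check_attrs <- function(node, tag, warnings) {
  have <- names(xml2::xml_attrs(node))
  extra <- setdiff(have, known_attrs[[tag]] %||% character(0))
  for (a in extra) {
    warnings$list[[length(warnings$list) + 1L]] <- diagnostic(
      "warning", tag, sprintf("unknown attribute '%s' on <%s> ignored", a, tag))
  }
}

parse_window_element <- function(node, warnings) {
  tag <- xml2::xml_name(node)
  if (!tag %in% WINDOW_TAGS)
    stop(sprintf("unknown window element <%s>", tag), call. = FALSE)
  check_attrs(node, tag, warnings)
  id <- attr_or_null(node, "id")
  switch(tag,
    label = new_window_element("label",
                               label = xml2::xml_text(node)),
    input = new_window_element("input", id = id,
                               label = attr_or_null(node, "label"),
                               default = attr_or_null(node, "default"),
                               hint = attr_or_null(node, "hint"),
                               secret = identical(attr_or_null(node, "secret"),
                                                  "true")),
    checkbox = new_window_element("checkbox", id = id,
                                  label = attr_or_null(node, "label"),
                                  default = attr_or_null(node, "default"),
                                  hint = attr_or_null(node, "hint")),
    filedialog = new_window_element("filedialog", id = id,
                                    label = attr_or_null(node, "label"),
                                    mode = attr_or_null(node, "mode") %||% "open",
                                    default = attr_or_null(node, "default"),
                                    hint = attr_or_null(node, "hint")),
    combobox = {
      opts <- vapply(xml2::xml_find_all(node, "./option"), xml2::xml_text,
                     character(1))
      new_window_element("combobox", id = id,
                         label = attr_or_null(node, "label"),
                         default = attr_or_null(node, "default"),
                         hint = attr_or_null(node, "hint"),
                         options = as.list(opts))
    },
    group = {
      kids <- lapply(xml2::xml_find_all(node, "./*"),
                     parse_window_element, warnings = warnings)
      new_window_element("group", id = id,
                         title = attr_or_null(node, "title"),
                         checkable = identical(attr_or_null(node, "checkable"),
                                               "true"),
                         layout = attr_or_null(node, "layout") %||% "vertical",
                         children = kids)
    },
    action = new_window_element("action",
                                label = attr_or_null(node, "label") %||% "Run"),
    streambox = new_window_element("streambox", id = id)
  )
}

# Parse mixed element/text content into a fragment. Text nodes inside
# fragment containers are kept verbatim (they carry ${refs} and literal
# punctuation); empty text nodes are dropped.
parse_fragment <- function(node, warnings) {
  parts <- list()
  for (child in xml2::xml_contents(node)) {
    if (inherits(child, "xml_node") &&
        xml2::xml_type(child) == "element") {
      parts[[length(parts) + 1L]] <- frag_node(
        parse_exec_node(child, warnings))
    } else {
      txt <- xml2::xml_text(child)
      if (nzchar(txt))
        parts[[length(parts) + 1L]] <- frag_text(txt)
    }
  }
  parts
}

parse_exec_node <- function(node, warnings) {
  tag <- xml2::xml_name(node)
  if (!tag %in% EXEC_TAGS)
    stop(sprintf("unknown execution node <%s>", tag), call. = FALSE)
  check_attrs(node, tag, warnings)
  id <- attr_or_null(node, "id")
  switch(tag,
    const = new_exec_node("const", id = id,
                          value = attr_or_null(node, "value") %||%
                            xml2::xml_text(node)),
    add = new_exec_node("add", id = id,
                        sep = attr_or_null(node, "sep") %||% "",
                        parts = parse_fragment(node, warnings)),
    env = {
      key <- attr_or_null(node, "key")
      if (is.null(key))
        stop("<env> node requires a 'key' attribute", call. = FALSE)
      new_exec_node("env", id = id, key = key)
    },
    "if" = {
      probe <- attr_or_null(node, "probe")
      if (is.null(probe))
        stop("<if> node requires a 'probe' attribute", call. = FALSE)
      then_el <- xml2::xml_find_first(node, "./then")
      if (inherits(then_el, "xml_missing"))
        stop("<if> node requires a <then> child", call. = FALSE)
      else_el <- xml2::xml_find_first(node, "./else")
      new_exec_node("if", id = id, probe = probe,
                    equals = attr_or_null(node, "equals") %||% "",
                    then = parse_fragment(then_el, warnings),
                    else_ = if (!inherits(else_el, "xml_missing"))
                      parse_fragment(else_el, warnings))
    },
    script = {
      argv_raw <- attr_or_null(node, "argv") %||% ""
      argv <- if (nzchar(argv_raw))
        trimws(strsplit(argv_raw, ",", fixed = TRUE)[[1]]) else character(0)
      new_exec_node("script", id = id, argv = as.list(argv),
                    dialect = attr_or_null(node, "dialect") %||% "lua",
                    source = xml2::xml_text(node))
    },
    execute = {
      program <- attr_or_null(node, "program")
      if (is.null(program))
        stop("<execute> node requires a 'program' attribute", call. = FALSE)
      params <- lapply(xml2::xml_find_all(node, "./param"), function(p) {
        check_attrs(p, "param", warnings)
        list(quote = attr_or_null(p, "quote"),
             fragment = parse_fragment(p, warnings))
      })
      new_exec_node("execute", id = id, program = program, params = params)
    }
  )
}

#' Parse a template document
#'
#' Reads the two-part XML template dialect: a `<window>` form model and an
#' `<execution>` dataflow model. Document order of elements and nodes is
#' preserved. Unknown tags are errors; unknown attributes are collected as
#' warning diagnostics (retrievable via `attr(t, "parse_warnings")`).
#'
#' @param doc XML text, a file path, or a connection accepted by
#'   [xml2::read_xml()].
#' @return A `forge_template`.
#' @seealso [validate_template()], [serialize_template()], [to_form_schema()]
#' @export
parse_template <- function(doc) {
  root <- tryCatch(xml2::read_xml(doc),
                   error = function(e) stop("XML parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(root) != "template")
    stop("document root must be <template>, found <",
         xml2::xml_name(root), ">", call. = FALSE)
  warnings <- new.env(parent = emptyenv())
  warnings$list <- list()
  check_attrs(root, "template", warnings)
  win_el <- xml2::xml_find_first(root, "./window")
  exe_el <- xml2::xml_find_first(root, "./execution")
  if (inherits(win_el, "xml_missing"))
    stop("template requires a <window> section", call. = FALSE)
  if (inherits(exe_el, "xml_missing"))
    stop("template requires an <execution> section", call. = FALSE)
  for (child in xml2::xml_find_all(root, "./*")) {
    nm <- xml2::xml_name(child)
    if (!nm %in% c("window", "execution"))
      stop(sprintf("unknown section <%s> under <template>", nm), call. = FALSE)
  }
  window <- lapply(xml2::xml_find_all(win_el, "./*"),
                   parse_window_element, warnings = warnings)
  execution <- lapply(xml2::xml_find_all(exe_el, "./*"),
                      parse_exec_node, warnings = warnings)
  t <- new_template(id = attr_or_null(root, "id") %||% "template",
                    title = attr_or_null(root, "title") %||% "",
                    description = attr_or_null(root, "description") %||% "",
                    window = window, execution = execution)
  attr(t, "parse_warnings") <- warnings$list
  t
}

# ---- reference scanning ----------------------------------------------------

#' Extract `${id}` references from text
#'
#' Implements the reference grammar used throughout the execution model:
#' `${` IDENT `}` with IDENT = `[A-Za-z_][A-Za-z0-9_]*`; `$$` escapes a
#' literal dollar.
#'
#' @param text character scalar.
#' @return character vector of referenced identifiers (in order, duplicated
#'   references repeated).
#' @keywords internal
scan_refs <- function(text) {
  refs <- character(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "$" && i < n && chars[i + 1L] == "$") {
      i <- i + 2L
    } else if (chars[i] == "$" && i < n && chars[i + 1L] == "{") {
      j <- i + 2L
      while (j <= n && chars[j] != "}") j <- j + 1L
      if (j > n)
        stop("unterminated ${ reference in: ", text, call. = FALSE)
      ident <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
      if (!grepl(IDENT_RE, ident))
        stop("invalid reference identifier '", ident, "'", call. = FALSE)
      refs <- c(refs, ident)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  refs
}

fragment_refs <- function(parts) {
  out <- character(0)
  for (p in parts) {
    if (p$type == "text") out <- c(out, scan_refs(p$text))
    else out <- c(out, node_refs(p$node))
  }
  out
}

# direct references of a node (not transitive); inline children contribute
# their own references because they are evaluated in place
node_refs <- function(node) {
  switch(node$kind,
    const = character(0),
    env = character(0),
    add = fragment_refs(node$parts),
    "if" = c(scan_refs(node$probe), fragment_refs(node$then),
             if (!is.null(node$else_)) fragment_refs(node$else_)),
    script = unlist(lapply(node$argv, scan_refs)) %||% character(0),
    execute = {
      out <- scan_refs(node$program)
      for (p in node$params) out <- c(out, fragment_refs(p$fragment))
      out
    })
}

window_elements_flat <- function(window) {
  out <- list()
  walk <- function(els) {
    for (el in els) {
      out[[length(out) + 1L]] <<- el
      if (!is.null(el$children)) walk(el$children)
    }
  }
  walk(window)
  out
}

# ids whose value can be referenced / must be bound: inputs, checkboxes,
# file dialogs, comboboxes and checkable groups
bindable_ids <- function(window) {
  els <- window_elements_flat(window)
  ids <- character(0)
  for (el in els) {
    if (is.null(el$id)) next
    if (el$kind %in% BINDABLE_KINDS ||
        (el$kind == "group" && isTRUE(el$checkable)))
      ids <- c(ids, el$id)
  }
  ids
}

all_window_ids <- function(window) {
  els <- window_elements_flat(window)
  ids <- vapply(els, function(el) el$id %||% NA_character_, character(1))
  ids[!is.na(ids)]
}

exec_node_ids <- function(execution) {
  ids <- vapply(execution, function(n) n$id %||% NA_character_, character(1))
  ids[!is.na(ids)]
}

#' Validate a template
#'
#' Checks the structural invariants the engine relies on: unique ids across
#' the window and execution models, every `${ref}` resolving to a bindable
#' window element or an execution node, an acyclic node graph, exactly one
#' action button and at least one execute node. Parse-time warnings (unknown
#' attributes) are appended as warning diagnostics.
#'
#' @param t a `forge_template`.
#' @return A list of `forge_diagnostic`; empty iff the template is valid
#'   (no error-severity diagnostics and no warnings).
#' @export
validate_template <- function(t) {
  stopifnot(inherits(t, "forge_template"))
  diags <- list()
  err <- function(loc, msg)
    diags[[length(diags) + 1L]] <<- diagnostic("error", loc, msg)

  win_ids <- all_window_ids(t$window)
  node_ids <- exec_node_ids(t$execution)
  all_ids <- c(win_ids, node_ids)
  for (dup in unique(all_ids[duplicated(all_ids)]))
    err(dup, sprintf("duplicate id '%s'", dup))

  for (id in all_ids)
    if (!grepl(IDENT_RE, id))
      err(id, sprintf("id '%s' is not a valid identifier", id))

  n_action <- sum(vapply(window_elements_flat(t$window),
                         function(el) el$kind == "action", logical(1)))
  if (n_action != 1L)
    err("window", sprintf("expected exactly one action button, found %d",
                          n_action))
  if (!any(vapply(t$execution, function(n) n$kind == "execute", logical(1))))
    err("execution", "execution model has no execute node")

  referenceable <- c(bindable_ids(t$window), node_ids)
  # resolve references; collect node->node edges for the cycle check
  edges <- list()
  for (node in t$execution) {
    loc <- node$id %||% node$kind
    refs <- tryCatch(node_refs(node), error = function(e) {
      err(loc, conditionMessage(e))
      character(0)
    })
    for (r in unique(refs))
      if (!r %in% referenceable)
        err(loc, sprintf("unresolved reference '${%s}'", r))
    if (!is.null(node$id))
      edges[[node$id]] <- intersect(unique(refs), node_ids)
  }

  # cycle detection over named node edges (DFS, three colours)
  colour <- new.env(parent = emptyenv())
  cycle_found <- FALSE
  visit <- function(id) {
    if (cycle_found) return(invisible())
    state <- get0(id, envir = colour, ifnotfound = "white")
    if (state == "grey") {
      cycle_found <<- TRUE
      err(id, sprintf("cycle in execution graph involving '%s'", id))
      return(invisible())
    }
    if (state == "black") return(invisible())
    assign(id, "grey", envir = colour)
    for (dep in edges[[id]] %||% character(0)) visit(dep)
    assign(id, "black", envir = colour)
  }
  for (id in names(edges)) visit(id)

  c(diags, attr(t, "parse_warnings") %||% list())
}

#' Quick validity predicate
#' @param t a `forge_template`.
#' @return `TRUE` iff [validate_template()] reports no error.
#' @export
template_is_valid <- function(t) {
  !any(vapply(validate_template(t),
              function(d) d$severity == "error", logical(1)))
}

# ---- serialization ---------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

attr_escape <- function(x) gsub("\"", "&quot;", xml_escape(x), fixed = TRUE)

tag_open <- function(tag, attrs) {
  keep <- !vapply(attrs, is.null, logical(1))
  attrs <- attrs[keep]
  if (length(attrs) == 0) return(paste0("<", tag, ">"))
  paste0("<", tag, " ",
         paste(sprintf("%s=\"%s\"", names(attrs),
                       vapply(attrs, function(v) attr_escape(as.character(v)),
                              character(1))),
               collapse = " "),
         ">")
}

leaf <- function(tag, attrs, content = NULL) {
  keep <- !vapply(attrs, is.null, logical(1))
  attrs <- attrs[keep]
  a <- if (length(attrs))
    paste0(" ", paste(sprintf("%s=\"%s\"", names(attrs),
                              vapply(attrs,
                                     function(v) attr_escape(as.character(v)),
                                     character(1))),
                      collapse = " "))
  else ""
  if (is.null(content)) sprintf("<%s%s/>", tag, a)
  else sprintf("<%s%s>%s</%s>", tag, a, content, tag)
}

serialize_window_element <- function(el) {
  switch(el$kind,
    label = leaf("label", list(), xml_escape(el$label %||% "")),
    input = leaf("input", list(id = el$id, label = el$label,
                               default = el$default, hint = el$hint,
                               secret = if (isTRUE(el$secret)) "true")),
    checkbox = leaf("checkbox", list(id = el$id, label = el$label,
                                     default = el$default, hint = el$hint)),
    filedialog = leaf("filedialog", list(id = el$id, label = el$label,
                                         mode = el$mode,
                                         default = el$default,
                                         hint = el$hint)),
    combobox = leaf("combobox", list(id = el$id, label = el$label,
                                     default = el$default, hint = el$hint),
                    paste(vapply(el$options, function(o)
                      leaf("option", list(), xml_escape(o)), character(1)),
                      collapse = "")),
    group = paste0(tag_open("group",
                            list(id = el$id, title = el$title,
                                 checkable = if (isTRUE(el$checkable)) "true",
                                 layout = el$layout)),
                   paste(vapply(el$children, serialize_window_element,
                                character(1)), collapse = ""),
                   "</group>"),
    action = leaf("action", list(label = el$label)),
    streambox = leaf("streambox", list(id = el$id)),
    stop("unknown window element kind: ", el$kind)
  )
}

serialize_fragment <- function(parts) {
  paste(vapply(parts, function(p) {
    if (p$type == "text") xml_escape(p$text)
    else serialize_exec_node(p$node)
  }, character(1)), collapse = "")
}

serialize_exec_node <- function(node) {
  switch(node$kind,
    const = leaf("const", list(id = node$id, value = node$value)),
    add = leaf("add", list(id = node$id,
                           sep = if (nzchar(node$sep)) node$sep),
               serialize_fragment(node$parts)),
    env = leaf("env", list(id = node$id, key = node$key)),
    "if" = paste0(tag_open("if", list(id = node$id, probe = node$probe,
                                      equals = if (nzchar(node$equals))
                                        node$equals)),
                  leaf("then", list(), serialize_fragment(node$then)),
                  if (!is.null(node$else_))
                    leaf("else", list(), serialize_fragment(node$else_))
                  else "",
                  "</if>"),
    script = leaf("script",
                  list(id = node$id,
                       argv = if (length(node$argv))
                         paste(unlist(node$argv), collapse = ","),
                       dialect = node$dialect),
                  paste0("<![CDATA[", node$source, "]]>")),
    execute = paste0(tag_open("execute", list(id = node$id,
                                              program = node$program)),
                     paste(vapply(node$params, function(p)
                       leaf("param", list(quote = p$quote),
                            serialize_fragment(p$fragment)), character(1)),
                       collapse = ""),
                     "</execute>"),
    stop("unknown execution node kind: ", node$kind)
  )
}

#' Serialize a template back to XML text
#'
#' The output is canonical (no indentation inside mixed content) so that
#' `parse_template(serialize_template(t))` is structurally equal to `t`.
#'
#' @param t a `forge_template`.
#' @return XML text (character scalar).
#' @export
serialize_template <- function(t) {
  stopifnot(inherits(t, "forge_template"))
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         tag_open("template", list(id = t$id, title = t$title,
                                   description = if (nzchar(t$description))
                                     t$description)),
         "<window>",
         paste(vapply(t$window, serialize_window_element, character(1)),
               collapse = ""),
         "</window><execution>",
         paste(vapply(t$execution, serialize_exec_node, character(1)),
               collapse = ""),
         "</execution></template>\n")
}

#' Structural equality of two templates
#'
#' Compares the parsed representation, ignoring parse-time warning
#' annotations.
#' @param a,b `forge_template` objects.
#' @return logical scalar.
#' @export
template_equal <- function(a, b) {
  strip <- function(t) {
    attr(t, "parse_warnings") <- NULL
    t
  }
  identical(strip(a), strip(b))
}

# ---- form schema -----------------------------------------------------------

#' Export the window model as a neutral form schema
#'
#' A renderer-agnostic, ordered description of the form: one entry per
#' window element in document order, with nesting mirroring group boxes.
#' File dialogs are flagged `pathTyped`; labels and stream boxes carry no
#' binding key.
#'
#' @param t a valid `forge_template`.
#' @return A `forge_form_schema`: list with `template` (id) and `entries`.
#' @export
to_form_schema <- function(t) {
  stopifnot(inherits(t, "forge_template"))
  entry <- function(el) {
    bindable <- el$kind %in% BINDABLE_KINDS ||
      (el$kind == "group" && isTRUE(el$checkable))
    e <- list(
      id = if (bindable) el$id else NULL,
      kind = el$kind,
      label = el$label %||% el$title,
      hint = el$hint,
      default = el$default %||%
        (if (el$kind == "checkbox" ||
             (el$kind == "group" && isTRUE(el$checkable))) "FALSE"
         else if (el$kind == "combobox" && length(el$options))
           el$options[[1]]),
      required = bindable && is.null(el$default) &&
        el$kind %in% c("input", "filedialog"),
      pathTyped = el$kind == "filedialog",
      secret = isTRUE(el$secret),
      options = el$options,
      checkable = if (el$kind == "group") isTRUE(el$checkable),
      children = if (!is.null(el$children)) lapply(el$children, entry)
    )
    e
  }
  structure(list(template = t$id, entries = lapply(t$window, entry)),
            class = "forge_form_schema")
}

#' Binding keys of a form schema
#'
#' @param schema a `forge_form_schema`.
#' @return character vector of element ids that expect a value, in document
#'   order.
#' @export
form_schema_binding_keys <- function(schema) {
  keys <- character(0)
  walk <- function(entries) {
    for (e in entries) {
      if (!is.null(e$id)) keys <<- c(keys, e$id)
      if (!is.null(e$children)) walk(e$children)
    }
  }
  walk(schema$entries)
  keys
}

#' @export
print.forge_form_schema <- function(x, ...) {
  cat(sprintf("<form schema> template '%s', %d binding keys: %s\n",
              x$template, length(form_schema_binding_keys(x)),
              paste(form_schema_binding_keys(x), collapse = ", ")))
  invisible(x)
}

#' Serialize a form schema as JSON
#' @param schema a `forge_form_schema`.
#' @return JSON text.
#' @export
form_schema_json <- function(schema) {
  drop_null <- function(x) {
    if (is.list(x) && is.null(names(x))) return(lapply(x, drop_null))
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      return(lapply(x, drop_null))
    }
    x
  }
  jsonlite::toJSON(drop_null(unclass(schema)), auto_unbox = TRUE,
                   pretty = TRUE)
}
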