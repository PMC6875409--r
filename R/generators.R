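# Template generators: from neutral CLI-parser specifications (CliSpec) and
# from CWL CommandLineTool documents.
#
# The generator's job is mechanical: one form widget per declared input,
# one execute node whose params re-emit flags and positionals, and the
# fallback rule — any input whose type cannot be recognised becomes a plain
# text input.

VALUE_TYPES <- c("boolean", "integer", "float", "string", "file",
                 "directory", "choice", "unknown")

#' Construct a neutral CLI-parser specification
#'
#' The intermediate form both generator front ends produce: a tool name,
#' base command and a list of inputs with types, flags, defaults and help
#' text. Validated on construction.
#'
#' @param tool_name tool name.
#' @param base_command character vector, the fixed leading argv (program
#'   first).
#' @param inputs list of input descriptions; each a list with `name`
#'   (required), and optionally `flag`, `value_type` (one of boolean,
#'   integer, float, string, file, directory, choice, unknown), `required`,
#'   `default`, `help`, `position`, `options` (for choice).
#' @param description free-text description.
#' @param subcommands optional list of `forge_cli_spec` for subcommands.
#' @return A `forge_cli_spec`.
#' @export
cli_spec <- function(tool_name, base_command, inputs = list(),
                     description = "", subcommands = list()) {
  stopifnot(is.character(base_command), length(base_command) >= 1)
  inputs <- lapply(inputs, function(inp) {
    if (is.null(inp$name) || !nzchar(inp$name))
      stop("cli spec input requires a name", call. = FALSE)
    inp$value_type <- inp$value_type %||% "unknown"
    if (!inp$value_type %in% VALUE_TYPES)
      stop(sprintf("unknown value type '%s' for input '%s'",
                   inp$value_type, inp$name), call. = FALSE)
    if (inp$value_type == "choice" && length(inp$options %||% list()) == 0)
      stop(sprintf("choice input '%s' requires non-empty options",
                   inp$name), call. = FALSE)
    inp$required <- isTRUE(inp$required)
    inp
  })
  nms <- vapply(inputs, function(i) i$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate input name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  structure(list(tool_name = tool_name, description = description,
                 base_command = base_command, inputs = inputs,
                 subcommands = subcommands),
            class = "forge_cli_spec")
}

#' @export
print.forge_cli_spec <- function(x, ...) {
  cat(sprintf("<cli spec> %s: %d input(s), %d subcommand(s)\n",
              x$tool_name, length(x$inputs), length(x$subcommands)))
  invisible(x)
}

#' Widget kind for a value type
#'
#' The fixed mapping table: booleans become check boxes, files and
#' directories file dialogs, enumerations combo boxes, numbers and strings
#' text inputs — and any unrecognised type falls back to a text input, so a
#' widget always exists.
#'
#' @param value_type one of the CliSpec value types (anything else maps to
#'   the text-input fallback).
#' @return character scalar: a window element kind.
#' @export
widget_for <- function(value_type) {
  switch(value_type,
    boolean = "checkbox",
    file = "filedialog",
    directory = "filedialog",
    choice = "combobox",
    integer = "textinput",
    float = "textinput",
    string = "textinput",
    "textinput")
}

widget_element <- function(inp, id = inp$name) {
  lbl <- widget_label(inp)
  switch(widget_for(inp$value_type),
    checkbox = new_window_element("checkbox", id = id, label = lbl,
                                  default = inp$default %||% "FALSE",
                                  hint = inp$help),
    filedialog = new_window_element("filedialog", id = id, label = lbl,
                                    mode = "open",
                                    default = inp$default,
                                    hint = inp$help),
    combobox = new_window_element("combobox", id = id, label = lbl,
                                  default = inp$default,
                                  hint = inp$help,
                                  options = as.list(unlist(inp$options))),
    new_window_element("input", id = id, label = lbl,
                       default = inp$default, hint = inp$help)
  )
}

# label policy: help text (truncated) when present, else the name
widget_label <- function(inp) {
  h <- inp$help
  if (!is.null(h) && nzchar(h)) {
    h <- gsub("\\s+", " ", trimws(h))
    if (nchar(h) > 60) h <- paste0(substr(h, 1, 57), "...")
    h
  } else inp$name
}

# sanitize a name into a reference identifier
make_ident <- function(x) {
  id <- gsub("[^A-Za-z0-9_]", "_", x)
  if (!grepl("^[A-Za-z_]", id)) id <- paste0("x_", id)
  id
}

# execution-model params for one input bound to element `id`
input_params <- function(inp, id) {
  if (inp$value_type == "boolean") {
    # flag gated on the checkbox: emitted on TRUE, nothing on FALSE
    cond <- new_exec_node("if", probe = sprintf("${%s}", id),
                          equals = "TRUE",
                          then = list(frag_text(inp$flag %||%
                                                  paste0("--", inp$name))),
                          else_ = NULL)
    return(list(list(quote = NULL, fragment = list(frag_node(cond)))))
  }
  if (!is.null(inp$flag)) {
    value_frag <- sprintf("%s ${%s}", inp$flag, id)
    if (inp$required)
      return(list(list(quote = NULL, fragment = list(frag_text(value_frag)))))
    # optional: omit the flag entirely when the value is empty
    cond <- new_exec_node("if", probe = sprintf("${%s}", id), equals = "",
                          then = list(frag_text("")),
                          else_ = list(frag_text(value_frag)))
    return(list(list(quote = NULL, fragment = list(frag_node(cond)))))
  }
  list(list(quote = NULL, fragment = list(frag_text(sprintf("${%s}", id)))))
}

#' Generate a template from a CLI specification
#'
#' Produces one window element per input (spec order), an action button and
#' a stream box, and an execution model with a single execute node whose
#' params emit, per input: flag plus value for flagged inputs (optional
#' flagged inputs are omitted while their value is empty), bare values for
#' positionals in position order, and the flag alone — gated by a
#' conditional on `"TRUE"` — for booleans. Subcommands become a combo box
#' selecting among per-subcommand gated argument groups. The generated
#' template always passes [validate_template()].
#'
#' @param spec a `forge_cli_spec`.
#' @return A `forge_template`.
#' @export
from_cli_spec <- function(spec) {
  stopifnot(inherits(spec, "forge_cli_spec"))
  window <- list()
  if (nzchar(spec$description %||% ""))
    window[[length(window) + 1L]] <- new_window_element(
      "label", label = spec$description)

  ids <- vapply(spec$inputs, function(i) make_ident(i$name), character(1))
  if (anyDuplicated(ids))
    stop("duplicate input name(s) after identifier sanitization: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (k in seq_along(spec$inputs))
    window[[length(window) + 1L]] <- widget_element(spec$inputs[[k]],
                                                    id = ids[k])

  sub_names <- vapply(spec$subcommands, function(s) s$tool_name,
                      character(1))
  if (length(spec$subcommands)) {
    window[[length(window) + 1L]] <- new_window_element(
      "combobox", id = "subcommand", label = "Subcommand",
      options = as.list(sub_names), default = sub_names[1])
    for (k in seq_along(spec$subcommands)) {
      sub <- spec$subcommands[[k]]
      kids <- list()
      for (inp in sub$inputs)
        kids[[length(kids) + 1L]] <- widget_element(
          inp, id = paste0(make_ident(sub$tool_name), "_",
                           make_ident(inp$name)))
      window[[length(window) + 1L]] <- new_window_element(
        "group", title = paste("Options:", sub$tool_name),
        layout = "vertical", children = kids)
    }
  }
  window[[length(window) + 1L]] <- new_window_element("action", label = "Run")
  window[[length(window) + 1L]] <- new_window_element("streambox",
                                                      id = NULL)

  params <- list()
  for (extra in spec$base_command[-1])
    params[[length(params) + 1L]] <- list(quote = NULL,
                                          fragment = list(frag_text(extra)))
  if (length(spec$subcommands))
    params[[length(params) + 1L]] <- list(
      quote = NULL, fragment = list(frag_text("${subcommand}")))

  flagged <- Filter(function(k) is.null(spec$inputs[[k]]$position),
                    seq_along(spec$inputs))
  positional <- setdiff(seq_along(spec$inputs), flagged)
  positional <- positional[order(vapply(spec$inputs[positional],
                                        function(i) as.numeric(i$position),
                                        numeric(1)))]
  for (k in flagged)
    params <- c(params, input_params(spec$inputs[[k]], ids[k]))
  if (length(spec$subcommands)) {
    for (j in seq_along(spec$subcommands)) {
      sub <- spec$subcommands[[j]]
      sub_params_text <- character(0)
      # per-subcommand group assembled as one gated fragment
      sub_frag <- list()
      for (inp in sub$inputs) {
        sid <- paste0(make_ident(sub$tool_name), "_", make_ident(inp$name))
        for (p in input_params(inp, sid)) {
          if (length(sub_frag)) sub_frag[[length(sub_frag) + 1L]] <-
            frag_text(" ")
          sub_frag <- c(sub_frag, p$fragment)
        }
      }
      cond <- new_exec_node("if", probe = "${subcommand}",
                            equals = sub$tool_name,
                            then = sub_frag, else_ = NULL)
      params[[length(params) + 1L]] <- list(quote = NULL,
                                            fragment = list(frag_node(cond)))
    }
  }
  for (k in positional)
    params <- c(params, input_params(spec$inputs[[k]], ids[k]))

  execute <- new_exec_node("execute", id = "run",
                           program = spec$base_command[1], params = params)
  new_template(id = make_ident(spec$tool_name),
               title = spec$tool_name,
               description = spec$description %||% "",
               window = window,
               execution = list(execute))
}

# ---- CWL front end ---------------------------------------------------------

cwl_type_map <- c(boolean = "boolean", int = "integer", long = "integer",
                  float = "float", double = "float", string = "string",
                  File = "file", Directory = "directory")

# normalise one CWL type expression to (value_type, required, options)
cwl_value_type <- function(type) {
  required <- TRUE
  options <- NULL
  if (is.character(type) && length(type) == 1) {
    if (endsWith(type, "?")) {
      required <- FALSE
      type <- substr(type, 1, nchar(type) - 1L)
    }
    if (endsWith(type, "[]"))
      return(list(value_type = "unknown", required = required))
    vt <- cwl_type_map[[type]] %||% "unknown"
    return(list(value_type = vt, required = required))
  }
  if (is.list(type) && !is.null(type$type)) {
    if (identical(type$type, "enum")) {
      return(list(value_type = "choice", required = required,
                  options = as.list(unlist(type$symbols))))
    }
    return(list(value_type = "unknown", required = required))
  }
  if (is.list(type) || (is.character(type) && length(type) > 1)) {
    # union, e.g. ["null", "File"]: null marks the input optional
    parts <- if (is.character(type)) as.list(type) else type
    non_null <- Filter(function(p) !identical(p, "null"), parts)
    if (length(non_null) != length(parts)) required <- FALSE
    if (length(non_null) == 1)
      return(modifyList(cwl_value_type(non_null[[1]]),
                        list(required = required)))
    return(list(value_type = "unknown", required = required))
  }
  list(value_type = "unknown", required = required)
}

#' Read a CWL CommandLineTool document into a CLI specification
#'
#' Supports the v1.x CommandLineTool subset: `baseCommand`, `inputs` (map
#' or array form) with the primitive types boolean/int/long/float/double/
#' string/File/Directory, enums, optional types (`T?` or a union with
#' `null`), `inputBinding.prefix` and `.position`, and `doc`/`label` as
#' help text. Records, nested arrays and expressions map to the unknown
#' type (downstream: text-input fallback). Outputs, requirements and hints
#' are ignored with a warning diagnostic.
#'
#' @param doc path to a CWL YAML/JSON file, or YAML text.
#' @return A `forge_cli_spec`; warning diagnostics in
#'   `attr(spec, "warnings")`.
#' @export
from_cwl <- function(doc) {
  parsed <- if (is.character(doc) && length(doc) == 1 && file.exists(doc))
    yaml::read_yaml(doc)
  else yaml::yaml.load(paste(doc, collapse = "\n"))
  if (is.null(parsed$class))
    stop("unsupported document: missing 'class'", call. = FALSE)
  if (!identical(parsed$class, "CommandLineTool"))
    stop(sprintf("unsupported document class '%s' (only CommandLineTool)",
                 parsed$class), call. = FALSE)
  ver <- parsed$cwlVersion %||% ""
  if (nzchar(ver) && !grepl("^v1\\.", ver))
    stop(sprintf("unsupported cwlVersion '%s' (v1.x only)", ver),
         call. = FALSE)
  warnings <- list()
  for (ignored in c("outputs", "requirements", "hints", "arguments"))
    if (!is.null(parsed[[ignored]]) && length(parsed[[ignored]]))
      warnings[[length(warnings) + 1L]] <- diagnostic(
        "warning", ignored,
        sprintf("CWL '%s' section is ignored by the generator", ignored))

  base_command <- as.character(unlist(parsed$baseCommand %||% "tool"))
  tool_name <- parsed$id %||% parsed$label %||% base_command[1]

  inputs_raw <- parsed$inputs
  inputs <- list()
  if (is.null(inputs_raw) || length(inputs_raw) == 0) {
    warnings[[length(warnings) + 1L]] <- diagnostic(
      "warning", "inputs", "document declares no inputs")
  } else {
    # map form: named list; array form: list of lists with 'id'
    entries <- if (!is.null(names(inputs_raw)) &&
                   all(nzchar(names(inputs_raw)))) {
      lapply(names(inputs_raw), function(nm) {
        e <- inputs_raw[[nm]]
        if (!is.list(e)) e <- list(type = e)
        e$id <- nm
        e
      })
    } else inputs_raw
    for (e in entries) {
      vt <- cwl_value_type(e$type %||% "string")
      inputs[[length(inputs) + 1L]] <- list(
        name = e$id,
        flag = e$inputBinding$prefix,
        value_type = vt$value_type,
        options = vt$options,
        required = vt$required,
        default = if (!is.null(e$default)) as.character(e$default),
        help = e$doc %||% e$label,
        position = e$inputBinding$position)
    }
  }
  spec <- cli_spec(tool_name = tool_name, base_command = base_command,
                   inputs = inputs,
                   description = paste(parsed$doc %||% "", collapse = " "))
  attr(spec, "warnings") <- warnings
  spec
}
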