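# Script host: evaluate <script> nodes by calling the template-supplied
# `evaluate` function in a registered embedded dialect.

the_dialects <- new.env(parent = emptyenv())

#' Register a scripting dialect
#'
#' A dialect is a function `function(source, args, step_limit, time_limit)`
#' returning a list of values; the host takes the last value of the call
#' stack as the node's output. The package registers the `"lua"` dialect on
#' load.
#'
#' @param name dialect identifier (the `dialect` attribute of script nodes).
#' @param fn evaluator function.
#' @export
register_dialect <- function(name, fn) {
  assign(name, fn, envir = the_dialects)
  invisible(name)
}

#' List registered dialect names
#' @return character vector.
#' @export
list_dialects <- function() ls(the_dialects)

lua_dialect <- function(source, args, step_limit, time_limit) {
  state <- lua_new_state(step_limit = step_limit, time_limit = time_limit)
  state <- lua_run(source, state)
  fn <- state$globals$evaluate
  if (is.null(fn) || !(is.function(fn) ||
                       (is.list(fn) && identical(fn$tag, "lua_closure"))))
    stop("script error: source does not define an 'evaluate' function",
         call. = FALSE)
  lua_call_value(fn, as.list(args), state)
}

#' Evaluate a script node
#'
#' Calls the node's `evaluate` function with the already-substituted argv
#' values, in the node's dialect, inside a sandbox: the dialect environment
#' exposes only pure string/number primitives — no filesystem, process,
#' network or module access. Execution is bounded by a step budget and a
#' wall-clock limit.
#'
#' The last return value of the script's call stack, rendered as text, is
#' the node's token. A `nil`/absent result is an error; numbers and
#' booleans are coerced to their text form.
#'
#' @param node a script execution node (or any list with `source`,
#'   `dialect` fields).
#' @param args character vector of argument values, in argv order.
#' @param step_limit maximum interpreter steps (default 1e6).
#' @param time_limit wall-clock cap in seconds (default 5).
#' @return character scalar.
#' @export
evaluate_script <- function(node, args, step_limit = 1e6, time_limit = 5) {
  dialect <- node$dialect %||% "lua"
  fn <- the_dialects[[dialect]]
  if (is.null(fn))
    stop(sprintf("unknown script dialect '%s' (registered: %s)", dialect,
                 paste(list_dialects(), collapse = ", ")), call. = FALSE)
  values <- fn(node$source, args, step_limit, time_limit)
  if (length(values) == 0L)
    stop("script error: evaluate returned no value", call. = FALSE)
  last <- values[[length(values)]]
  if (is.null(last))
    stop("script error: evaluate returned nil", call. = FALSE)
  lua_tostring(last)
}

.onLoad <- function(libname, pkgname) {
  register_dialect("lua", lua_dialect)
}
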