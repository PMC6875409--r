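# Install modules: POSIX-shell scripts that install an application into a
# chosen directory. The runner passes a fixed positional argument contract:
#
#   script  INSTALL_DIR  ADD_TO_PATH("TRUE"/"FALSE")  SUDO_PASSWORD  extras...
#
# Extras (declared additional inputs, e.g. an installer wheel) come strictly
# last, in declared order. A module may ship the template for the installed
# tool inside a delimited comment block; the runner extracts and registers
# it after a successful install.

TEMPLATE_BLOCK_BEGIN <- "### TEMPLATE-BEGIN"
TEMPLATE_BLOCK_END <- "### TEMPLATE-END"

#' Describe an install module
#'
#' @param script_path path to the module's shell script.
#' @param name module name (defaults to the script file name).
#' @param description free text.
#' @param declared_extras additional inputs whose values are appended to
#'   the invocation (order matters): either a character vector of input
#'   names or a list of window elements.
#' @param target_environments character vector, e.g. `"apt-based"`.
#' @return A `forge_install_module`.
#' @export
install_module <- function(script_path, name = NULL, description = "",
                           declared_extras = list(),
                           target_environments = "apt-based") {
  if (!file.exists(script_path))
    stop(sprintf("install module script not found: %s", script_path),
         call. = FALSE)
  if (is.character(declared_extras))
    declared_extras <- lapply(declared_extras, function(nm)
      new_window_element("input", id = nm, label = nm))
  reserved <- c("installdir", "addtopath", "sudopassword")
  for (el in declared_extras) {
    if (!is.null(el$id) && tolower(el$id) %in% reserved)
      stop(sprintf("extra input id '%s' collides with a reserved option",
                   el$id), call. = FALSE)
  }
  structure(list(script_path = script_path,
                 name = name %||% basename(script_path),
                 description = description,
                 declared_extras = declared_extras,
                 target_environments = target_environments),
            class = "forge_install_module")
}

#' @export
print.forge_install_module <- function(x, ...) {
  cat(sprintf("<install module> %s (%s), %d extra input(s)\n", x$name,
              paste(x$target_environments, collapse = ", "),
              length(x$declared_extras)))
  invisible(x)
}

#' Install options
#'
#' @param install_dir target directory (required, non-empty).
#' @param add_to_path should the tool be added to the user's PATH.
#' @param sudo_password optional secret; passed in the third positional
#'   slot (empty placeholder when absent) and additionally exported as the
#'   `FORGE_SUDO_PASSWORD` environment variable for modules that prefer
#'   reading it there. Never logged or persisted.
#' @param extras ordered character values for the module's declared extra
#'   inputs.
#' @return A `forge_install_options`.
#' @export
install_options <- function(install_dir, add_to_path = FALSE,
                            sudo_password = NULL, extras = character(0)) {
  if (is.null(install_dir) || !nzchar(install_dir))
    stop("install_dir must be a non-empty path", call. = FALSE)
  structure(list(install_dir = install_dir,
                 add_to_path = isTRUE(add_to_path),
                 sudo_password = sudo_password,
                 extras = as.character(extras)),
            class = "forge_install_options")
}

#' Build the install invocation
#'
#' Pure construction of the module call with the fixed positional
#' contract: `[install_dir, add_to_path as "TRUE"/"FALSE", sudo password or
#' empty placeholder, extras...]` — extras strictly last, order preserved.
#' The password slot index is recorded so display/serialization can mask
#' it.
#'
#' @param m a `forge_install_module`.
#' @param o a `forge_install_options`.
#' @return A `forge_invocation` whose `argv` holds the positional
#'   arguments.
#' @export
build_install_invocation <- function(m, o) {
  stopifnot(inherits(m, "forge_install_module"),
            inherits(o, "forge_install_options"))
  if (length(o$extras) > length(m$declared_extras))
    stop(sprintf("module declares %d extra input(s) but %d value(s) given",
                 length(m$declared_extras), length(o$extras)), call. = FALSE)
  argv <- c(o$install_dir,
            if (o$add_to_path) "TRUE" else "FALSE",
            o$sudo_password %||% "",
            o$extras)
  new_invocation(program = m$script_path,
                 argument_text = paste(argv, collapse = " "),
                 argv = argv,
                 secret_slots = if (!is.null(o$sudo_password)) 3L
                                else integer(0))
}

#' Extract the embedded template from an install module
#'
#' Scans the module script (or any captured output stream) for a delimited
#' block between `### TEMPLATE-BEGIN` and `### TEMPLATE-END` lines, strips
#' a leading comment marker per line, and parses the content as a template
#' document. Absence of a block is not an error.
#'
#' @param source path to a script file, or a character vector of lines.
#' @return A `forge_template`; `NULL` when no block is present; a
#'   `forge_extract_failure` (carrying a `forge_diagnostic`) when the block
#'   exists but its XML is malformed — the module stays usable for
#'   installation either way.
#' @export
extract_embedded_template <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source, warn = FALSE)
  else as.character(source)
  begin <- which(trimws(lines) == TEMPLATE_BLOCK_BEGIN)
  end <- which(trimws(lines) == TEMPLATE_BLOCK_END)
  if (length(begin) == 0 || length(end) == 0) return(NULL)
  begin <- begin[1]
  end <- end[end > begin][1]
  if (is.na(end)) return(NULL)
  if (end <= begin + 1L) return(NULL)
  block <- lines[(begin + 1L):(end - 1L)]
  block <- sub("^\\s*#\\s?", "", block)   # tolerate commented-out blocks
  t <- tryCatch(parse_template(paste(block, collapse = "\n")),
                error = function(e)
                  structure(list(), class = "forge_template_error",
                            msg = conditionMessage(e)))
  if (inherits(t, "forge_template_error")) {
    out <- list(template = NULL,
                diagnostic = diagnostic(
                  "error", "embedded-template",
                  paste("embedded template does not parse:",
                        attr(t, "msg"))))
    class(out) <- "forge_extract_failure"
    return(out)
  }
  t
}

#' @export
print.forge_extract_failure <- function(x, ...) {
  print(x$diagnostic)
  invisible(x)
}

#' Run an install module
#'
#' Builds the invocation, executes it via the chosen backend (native or
#' WSL), and — on success — extracts any embedded template from the script
#' and registers it in the store. A nonzero exit surfaces the run result
#' and registers nothing.
#'
#' @param m a `forge_install_module`.
#' @param o a `forge_install_options`.
#' @param store optional `forge_store` for template registration.
#' @param backend a `forge_backend` of kind native or wsl.
#' @param timeout seconds (passed to [execute()]).
#' @return list with `result` (a `forge_run_result`) and `template` (the
#'   registered `forge_template` or `NULL`).
#' @export
run_install <- function(m, o, store = NULL, backend = backend_native(),
                        timeout = 0) {
  stopifnot(inherits(m, "forge_install_module"),
            inherits(o, "forge_install_options"))
  if (!backend$kind %in% c("native", "wsl"))
    stop("install modules run via the native or wsl backend only",
         call. = FALSE)
  inv <- build_install_invocation(m, o)
  # argv execution path: call the script directly, no shell -c wrapping,
  # so positional arguments survive verbatim (including spaces)
  argv <- c(if (backend$kind == "wsl") c(backend$wsl_exe),
            "sh", m$script_path, inv$argv)
  if (!is.null(o$sudo_password)) {
    old <- Sys.getenv("FORGE_SUDO_PASSWORD", unset = NA)
    Sys.setenv(FORGE_SUDO_PASSWORD = o$sudo_password)
    on.exit({
      if (is.na(old)) Sys.unsetenv("FORGE_SUDO_PASSWORD")
      else Sys.setenv(FORGE_SUDO_PASSWORD = old)
    }, add = TRUE)
  }
  result <- execute(argv, timeout = timeout)
  registered <- NULL
  if (identical(result$exit_status, 0L)) {
    t <- extract_embedded_template(m$script_path)
    if (inherits(t, "forge_template")) {
      if (!is.null(store)) store_register(store, t, kind = "template")
      registered <- t
    }
  }
  list(result = result, template = registered)
}
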