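# Execution backends: turn an assembled invocation into a concrete runnable
# form (native shell, WSL, ssh, HTTP POST, Docker) and execute it with
# per-channel streamed output capture.

#' Backend descriptors
#'
#' Constructors for the five execution paths. Construction carries only the
#' data the path needs; exactly one kind per descriptor.
#'
#' @param shell shell executable used to start the command (default `"sh"`).
#' @return A `forge_backend`.
#' @export
backend_native <- function(shell = "sh") {
  structure(list(kind = "native", shell = shell), class = "forge_backend")
}

#' @rdname backend_native
#' @param wsl_exe the WSL entry-point executable (default `"wsl.exe"`).
#' @export
backend_wsl <- function(wsl_exe = "wsl.exe", shell = "sh") {
  structure(list(kind = "wsl", wsl_exe = wsl_exe, shell = shell),
            class = "forge_backend")
}

#' @rdname backend_native
#' @param host remote host name.
#' @param port optional ssh port.
#' @param transport `"ssh"` (command started remotely, output returned over
#'   the connection) or `"stream"` (remote stdout piped to a TCP listener).
#' @param stream_host,stream_port listener address for `transport =
#'   "stream"`.
#' @export
backend_remote <- function(host, port = NULL, transport = "ssh",
                           stream_host = NULL, stream_port = NULL) {
  stopifnot(transport %in% c("ssh", "stream"))
  structure(list(kind = "remote", host = host, port = port,
                 transport = transport, stream_host = stream_host,
                 stream_port = stream_port, shell = "sh"),
            class = "forge_backend")
}

#' @rdname backend_native
#' @param url endpoint receiving the POST request.
#' @param fields optional named mapping element-id -> form-field name;
#'   identity when omitted.
#' @export
backend_http <- function(url, fields = NULL) {
  if (is.null(url) || !nzchar(url))
    stop("http backend requires a URL", call. = FALSE)
  structure(list(kind = "http", url = url, fields = fields),
            class = "forge_backend")
}

#' @rdname backend_native
#' @param image Docker image to run.
#' @param mounts named character vector host-path -> container-path.
#' @param workdir optional working directory inside the container.
#' @export
backend_docker <- function(image, mounts = character(0), workdir = NULL,
                           shell = "sh") {
  if (is.null(image) || !nzchar(image))
    stop("docker backend requires an image", call. = FALSE)
  structure(list(kind = "docker", image = image, mounts = mounts,
                 workdir = workdir, shell = shell),
            class = "forge_backend")
}

#' @export
print.forge_backend <- function(x, ...) {
  cat(sprintf("<backend:%s>\n", x$kind))
  invisible(x)
}

#' Translate a Windows drive-letter path to its WSL (POSIX) form
#'
#' `X:\a\b` becomes `/mnt/x/a/b` (drive letter lowercased, backslashes
#' converted, spaces preserved), following the WSL `wslpath` convention.
#' Anything that does not start with a drive letter is returned unchanged;
#' the function is total.
#'
#' @param p character vector of paths.
#' @return character vector.
#' @seealso [translate_path_posix_to_win()]
#' @export
translate_path_win_to_posix <- function(p) {
  vapply(p, function(x) {
    if (!grepl("^[A-Za-z]:([\\\\/]|$)", x)) return(x)
    drive <- tolower(substr(x, 1, 1))
    rest <- substr(x, 3, nchar(x))
    rest <- gsub("\\", "/", rest, fixed = TRUE)
    if (!startsWith(rest, "/")) rest <- paste0("/", rest)
    paste0("/mnt/", drive, rest)
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a WSL mount path back to Windows form
#'
#' Inverse of [translate_path_win_to_posix()] on `/mnt/<drive>/...` paths
#' (drive letter uppercased, separators converted back to backslashes);
#' other inputs pass through unchanged.
#'
#' @param p character vector of paths.
#' @return character vector.
#' @export
translate_path_posix_to_win <- function(p) {
  vapply(p, function(x) {
    m <- regmatches(x, regexec("^/mnt/([a-zA-Z])(/.*)?$", x))[[1]]
    if (length(m) == 0) return(x)
    drive <- toupper(m[2])
    rest <- m[3]
    if (is.na(rest) || !nzchar(rest)) rest <- "/"
    paste0(drive, ":", gsub("/", "\\", rest, fixed = TRUE))
  }, character(1), USE.NAMES = FALSE)
}

#' Build the runnable form of an invocation for a backend
#'
#' Pure construction — no process is spawned. Native wraps the command in a
#' shell; WSL wraps the same command for the WSL entry point, with every
#' path-typed binding value pre-translated by
#' [translate_path_win_to_posix()] inside the argument text; remote (ssh)
#' wraps it for the remote host; HTTP yields a POST request descriptor with
#' the bindings as form fields; Docker prepends `docker run` with one `-v
#' host:container` per mount.
#'
#' @param inv a `forge_invocation`.
#' @param backend a `forge_backend` (defaults to the invocation's own).
#' @return A `forge_runnable`: either `argv` (character vector) or an HTTP
#'   `request` descriptor.
#' @export
build_backend_command <- function(inv, backend = NULL) {
  stopifnot(inherits(inv, "forge_invocation"))
  backend <- backend %||% inv$backend
  cmd <- command_text(inv)
  runnable <- switch(backend$kind,
    native = list(argv = c(backend$shell, "-c", cmd)),
    wsl = {
      translated <- cmd
      for (id in inv$bindings$path_typed %||% character(0)) {
        val <- inv$bindings$values[[id]]
        tr <- translate_path_win_to_posix(val)
        if (!identical(tr, val))
          translated <- gsub(val, tr, translated, fixed = TRUE)
      }
      list(argv = c(backend$wsl_exe, backend$shell, "-c", translated))
    },
    remote = {
      if (backend$transport == "stream") {
        piped <- sprintf("%s | nc %s %s", cmd,
                         backend$stream_host %||% "localhost",
                         backend$stream_port %||% 55025)
        list(argv = c("ssh",
                      if (!is.null(backend$port)) c("-p",
                                                    as.character(backend$port)),
                      backend$host, piped))
      } else {
        list(argv = c("ssh",
                      if (!is.null(backend$port)) c("-p",
                                                    as.character(backend$port)),
                      backend$host, cmd))
      }
    },
    http = {
      vals <- inv$bindings$values %||% list()
      fields <- if (!is.null(backend$fields)) {
        out <- list()
        for (id in names(backend$fields))
          if (id %in% names(vals)) out[[backend$fields[[id]]]] <- vals[[id]]
        out
      } else vals
      list(request = list(method = "POST", url = backend$url,
                          fields = fields,
                          content_type = "application/x-www-form-urlencoded"))
    },
    docker = {
      mount_args <- character(0)
      for (h in names(backend$mounts))
        mount_args <- c(mount_args, "-v",
                        paste0(h, ":", backend$mounts[[h]]))
      list(argv = c("docker", "run", mount_args,
                    if (!is.null(backend$workdir)) c("-w", backend$workdir),
                    backend$image, backend$shell, "-c", cmd))
    },
    stop("unknown backend kind: ", backend$kind)
  )
  structure(c(runnable, list(backend = backend$kind)),
            class = "forge_runnable")
}

command_text <- function(inv) {
  if (!is.null(inv$argv))
    return(paste(c(inv$program, inv$argv), collapse = " "))
  if (nzchar(inv$argument_text))
    paste(inv$program, inv$argument_text)
  else inv$program
}

#' @export
print.forge_runnable <- function(x, ...) {
  if (!is.null(x$argv))
    cat(sprintf("<runnable:%s> %s\n", x$backend,
                paste(x$argv, collapse = " ")))
  else
    cat(sprintf("<runnable:%s> %s %s\n", x$backend, x$request$method,
                x$request$url))
  invisible(x)
}

#' Execute a runnable and capture its output
#'
#' Runs the child process (or performs the HTTP exchange) to completion or
#' timeout. Output lines are captured per channel in arrival order; the
#' exit status is recorded. Execution only ever happens through this
#' function — assembly and backend construction are pure.
#'
#' @param runnable a `forge_runnable` from [build_backend_command()], or a
#'   plain character argv vector.
#' @param timeout seconds before the child is killed (0 = no limit).
#' @return A `forge_run_result`: `exit_status` (integer; 124 on timeout,
#'   127 when the program was not found), `records` (data.frame with
#'   `channel` in `out`/`err` and `line`), `timed_out` flag, `started` /
#'   `finished` timestamps.
#' @export
execute <- function(runnable, timeout = 0) {
  if (is.character(runnable))
    runnable <- structure(list(argv = runnable, backend = "native"),
                          class = "forge_runnable")
  stopifnot(inherits(runnable, "forge_runnable"))
  started <- Sys.time()
  if (!is.null(runnable$request)) {
    res <- execute_http(runnable$request)
    res$started <- started
    res$finished <- Sys.time()
    return(res)
  }
  argv <- runnable$argv
  out_file <- tempfile("forge-out-")
  err_file <- tempfile("forge-err-")
  on.exit(unlink(c(out_file, err_file)), add = TRUE)
  status <- tryCatch(
    suppressWarnings(system2(argv[1], shQuote(argv[-1]),
                             stdout = out_file, stderr = err_file,
                             timeout = timeout)),
    error = function(e) 127L
  )
  out_lines <- if (file.exists(out_file)) readLines(out_file, warn = FALSE)
               else character(0)
  err_lines <- if (file.exists(err_file)) readLines(err_file, warn = FALSE)
               else character(0)
  records <- rbind(
    if (length(out_lines))
      data.frame(channel = "out", line = out_lines,
                 stringsAsFactors = FALSE),
    if (length(err_lines))
      data.frame(channel = "err", line = err_lines,
                 stringsAsFactors = FALSE)
  )
  if (is.null(records))
    records <- data.frame(channel = character(0), line = character(0),
                          stringsAsFactors = FALSE)
  structure(list(exit_status = as.integer(status),
                 records = records,
                 timed_out = identical(as.integer(status), 124L) &&
                   timeout > 0,
                 started = started, finished = Sys.time()),
            class = "forge_run_result")
}

# HTTP POST via base R connections; the response body becomes out-records.
# Only exercised at run time against a live endpoint.
execute_http <- function(request) {
  body <- paste(vapply(names(request$fields), function(k)
    paste0(utils::URLencode(k, reserved = TRUE), "=",
           utils::URLencode(as.character(request$fields[[k]]),
                            reserved = TRUE)),
    character(1)), collapse = "&")
  lines <- tryCatch({
    con <- url(request$url, open = "rb",
               method = "libcurl",
               headers = c("Content-Type" = request$content_type))
    on.exit(close(con), add = TRUE)
    readLines(con, warn = FALSE)
  }, error = function(e) {
    return(structure(list(error = conditionMessage(e)), class = "http_err"))
  })
  if (inherits(lines, "http_err")) {
    return(structure(list(exit_status = NA_integer_,
                          records = data.frame(channel = "err",
                                               line = lines$error,
                                               stringsAsFactors = FALSE),
                          timed_out = FALSE),
                     class = "forge_run_result"))
  }
  structure(list(exit_status = NA_integer_,
                 records = data.frame(channel = rep("out", length(lines)),
                                      line = lines,
                                      stringsAsFactors = FALSE),
                 timed_out = FALSE, request_body = body),
            class = "forge_run_result")
}

#' @export
print.forge_run_result <- function(x, ...) {
  cat(sprintf("<run result> exit %s, %d record(s)%s\n",
              if (is.na(x$exit_status)) "NA (http)" else x$exit_status,
              nrow(x$records),
              if (isTRUE(x$timed_out)) " [timed out]" else ""))
  invisible(x)
}
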