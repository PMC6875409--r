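# Shared fixtures and independent oracles for the suite.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "cmdforge")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

fixture_template_files <- function() {
  vapply(c("stream-example.xml", "minimal.xml", "hisat-index.xml"),
         fixture_path, character(1))
}

stream_template <- function() parse_template(fixture_path("stream-example.xml"))

# Listing-style script node source: strips a numbered index-file extension
listing_source <- paste(
  "function evaluate(arg1)",
  "  if (string.match(arg1, \".%d.ht2$\")) then",
  "    return(string.sub(arg1, 0, arg1:find(\".%d.ht2$\")-1))",
  "  end",
  "  return(arg1)",
  "end", sep = "\n")

listing_node <- function() list(kind = "script", source = listing_source,
                                dialect = "lua")

# ---- pattern-dialect oracle ------------------------------------------------
# Independent reference: translate the pattern subset to a PCRE regex and
# let R's own regex engine find the leftmost match. Supports what the
# random generator emits: literals [a-z0-9], '.', classes %d %a %l %w %s,
# quantifiers * + - ?, anchors ^ $.
pattern_to_pcre <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "%" && i < n) {
      cls <- chars[i + 1L]
      out <- c(out, switch(cls,
        d = "[0-9]", a = "[A-Za-z]", l = "[a-z]", u = "[A-Z]",
        w = "[A-Za-z0-9]", s = "[ \t\n\r\f\v]",
        D = "[^0-9]", A = "[^A-Za-z]", L = "[^a-z]", U = "[^A-Z]",
        W = "[^A-Za-z0-9]", S = "[^ \t\n\r\f\v]",
        paste0("\\", cls)))
      i <- i + 2L
    } else if (ch == "-") {
      out[length(out)] <- paste0(out[length(out)], "*?")   # lazy star
      i <- i + 1L
    } else if (ch %in% c(".", "*", "+", "?", "^", "$")) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      out <- c(out, if (grepl("[A-Za-z0-9 ]", ch)) ch
               else paste0("\\", ch))
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

oracle_match <- function(s, pattern) {
  m <- regexpr(pattern_to_pcre(pattern), s, perl = TRUE)
  if (m < 0) return(NULL)
  c(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
}

random_filename <- function() {
  alphabet <- c(letters, 0:9, ".")
  n <- sample(1:14, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_pattern <- function() {
  atoms <- c("%d", "%a", "%l", "%w", ".", sample(c(letters, 0:9), 5))
  k <- sample(1:5, 1)
  body <- vapply(seq_len(k), function(i) {
    a <- sample(atoms, 1)
    q <- sample(c("", "", "", "*", "+", "-", "?"), 1)
    paste0(a, q)
  }, character(1))
  paste0(if (runif(1) < 0.2) "^" else "",
         paste(body, collapse = ""),
         if (runif(1) < 0.3) "$" else "")
}

# ---- random execution networks and the naive oracle ------------------------
# Generates an acyclic execution model over const/add/if/env nodes whose
# references only point backwards (to earlier nodes or window elements).
random_exec_model <- function(max_nodes = 30, n_elements = 3) {
  element_ids <- paste0("e", seq_len(n_elements))
  element_vals <- setNames(
    as.list(replicate(n_elements,
                      paste(sample(c(letters, "TRUE", "FALSE"), 2),
                            collapse = "_"))),
    element_ids)
  env_keys <- c("os", "home")
  env <- list(os = "Linux", home = "/home/u")
  n <- sample(2:max_nodes, 1)
  nodes <- list()
  for (k in seq_len(n)) {
    id <- paste0("n", k)
    avail <- c(element_ids, if (k > 1) paste0("n", seq_len(k - 1)))
    kind <- sample(c("const", "add", "if", "env"), 1,
                   prob = c(0.3, 0.35, 0.25, 0.1))
    nodes[[k]] <- switch(kind,
      const = list(kind = "const", id = id,
                   value = paste(sample(letters, 3), collapse = "")),
      env = list(kind = "env", id = id, key = sample(env_keys, 1)),
      add = {
        nparts <- sample(1:3, 1)
        parts <- lapply(seq_len(nparts), function(j) {
          ref <- sample(avail, 1)
          list(type = "text",
               text = sprintf("%s${%s}", sample(c("", "x-"), 1), ref))
        })
        list(kind = "add", id = id, sep = sample(c("", " ", ","), 1),
             parts = parts)
      },
      "if" = {
        probe_ref <- sample(avail, 1)
        list(kind = "if", id = id,
             probe = sprintf("${%s}", probe_ref),
             equals = sample(c("TRUE", "abc", ""), 1),
             then = list(list(type = "text",
                              text = sprintf("T${%s}", sample(avail, 1)))),
             else_ = if (runif(1) < 0.7)
               list(list(type = "text",
                         text = sprintf("F${%s}", sample(avail, 1)))))
      })
    class(nodes[[k]]) <- "forge_exec_node"
  }
  # terminal execute node referencing the last node
  nodes[[n + 1L]] <- structure(
    list(kind = "execute", id = "run", program = "echo",
         params = list(list(quote = NULL,
                            fragment = list(list(type = "text",
                                                 text = sprintf("${n%d}",
                                                                n)))))),
    class = "forge_exec_node")
  list(model = nodes, element_vals = element_vals, env = env)
}

# Naive reference evaluator: plain recursion over the node list, no
# memoization, no engine machinery. Re-evaluates on every reference.
naive_eval <- function(model, element_vals, env) {
  by_id <- list()
  for (nd in model) if (!is.null(nd$id)) by_id[[nd$id]] <- nd
  subst <- function(text) {
    out <- ""
    i <- 1L
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    while (i <= length(chars)) {
      if (chars[i] == "$" && i < length(chars) && chars[i + 1L] == "{") {
        j <- i + 2L
        while (chars[j] != "}") j <- j + 1L
        ref <- paste(chars[(i + 2L):(j - 1L)], collapse = "")
        out <- paste0(out, resolve(ref))
        i <- j + 1L
      } else {
        out <- paste0(out, chars[i])
        i <- i + 1L
      }
    }
    out
  }
  resolve <- function(ref) {
    if (ref %in% names(element_vals)) return(element_vals[[ref]])
    ev(by_id[[ref]])
  }
  frag <- function(parts)
    paste(vapply(parts, function(p) subst(p$text), character(1)),
          collapse = "")
  ev <- function(nd) {
    switch(nd$kind,
      const = nd$value,
      env = as.character(env[[nd$key]]),
      add = paste(vapply(nd$parts, function(p) subst(p$text), character(1)),
                  collapse = nd$sep),
      "if" = if (identical(subst(nd$probe), nd$equals)) frag(nd$then)
             else if (!is.null(nd$else_)) frag(nd$else_) else "",
      execute = frag(nd$params[[1]]$fragment))
  }
  vals <- list()
  for (nd in model) if (!is.null(nd$id)) vals[[nd$id]] <- ev(nd)
  vals
}

make_bindings <- function(values, path_typed = character(0),
                          secret = character(0)) {
  structure(list(values = lapply(values, as.character),
                 path_typed = path_typed, secret = secret),
            class = "forge_bindings")
}

# ---- random CLI specs ------------------------------------------------------
random_cli_spec <- function(k = NULL) {
  types <- c("boolean", "integer", "float", "string", "file", "directory",
             "choice", "unknown")
  k <- k %||% sample(1:8, 1)
  inputs <- lapply(seq_len(k), function(j) {
    vt <- sample(types, 1)
    flagged <- runif(1) < 0.7 || vt == "boolean"
    list(name = paste0("opt", j),
         flag = if (flagged) paste0("--opt", j),
         value_type = vt,
         required = runif(1) < 0.5,
         options = if (vt == "choice") list("alpha", "beta"),
         help = if (runif(1) < 0.5) paste("option number", j),
         position = if (!flagged) j)
  })
  cli_spec(tool_name = paste0("tool", sample(1000, 1)),
           base_command = "tool",
           inputs = inputs,
           description = "randomly generated specification")
}

all_bindings_for_spec <- function(spec, t) {
  raw <- list()
  for (inp in spec$inputs) {
    raw[[inp$name]] <- switch(inp$value_type,
      boolean = "TRUE",
      choice = unlist(inp$options)[1],
      integer = "7",
      float = "0.5",
      paste0("v_", inp$name))
  }
  collect_bindings(t$window, raw)
}

# ---- random windows paths --------------------------------------------------
random_win_path <- function() {
  drive <- sample(LETTERS, 1)
  depth <- sample(0:6, 1)
  if (depth == 0) return(paste0(drive, ":\\"))
  parts <- vapply(seq_len(depth), function(i) {
    n <- sample(1:8, 1)
    paste(sample(c(letters, LETTERS, 0:9, " "), n, replace = TRUE),
          collapse = "")
  }, character(1))
  # no trailing/leading spaces in components (not representable reliably)
  parts <- vapply(parts, function(p) {
    p <- gsub("^ +| +$", "", p)
    if (!nzchar(p)) "x" else p
  }, character(1))
  paste0(drive, ":\\", paste(parts, collapse = "\\"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
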