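# Embedded scripting dialect: a sandboxed interpreter for the Lua subset
# that template script nodes use, plus the Lua-style pattern matcher.
#
# The interpreter supports: function definitions, local/global assignment,
# if/elseif/else, while, return (with multiple values; call-stack semantics
# as in Lua: an expression list truncates all but its last expression to one
# value), the operators and/or/not, comparison, concatenation (..),
# arithmetic, string method-call sugar (s:find(p)), and a string library
# (match, find, sub, len, upper, lower, rep, gsub) backed by the pattern
# matcher below. There is deliberately no io, os, require, load or
# filesystem access: scripts are pure string functions. Execution is capped
# by a step counter and a wall-clock deadline.

# ---- pattern matcher -------------------------------------------------------

# Compile a Lua pattern into a list of single-char matchers with
# quantifiers. Supported: literal characters, '.', %classes
# (a c d l p s u w x and uppercase complements, %<punct> literal escape),
# [sets] with ranges and ^ negation, quantifiers * + - ?, anchors ^ (start,
# only at pattern start) and $ (end, only at pattern end).
compile_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(chars)
  anchored_start <- FALSE
  i <- 1L
  if (n >= 1L && chars[1] == "^") {
    anchored_start <- TRUE
    i <- 2L
  }
  items <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch == "$" && i == n) {
      items[[length(items) + 1L]] <- list(type = "end")
      i <- i + 1L
      next
    }
    if (ch == "%") {
      if (i == n) stop("malformed pattern: ends with '%'", call. = FALSE)
      cls <- chars[i + 1L]
      item <- list(type = "class", class = cls)
      i <- i + 2L
    } else if (ch == "[") {
      j <- i + 1L
      negate <- FALSE
      if (j <= n && chars[j] == "^") {
        negate <- TRUE
        j <- j + 1L
      }
      set_items <- list()
      first <- TRUE
      repeat {
        if (j > n) stop("malformed pattern: unfinished '['", call. = FALSE)
        if (chars[j] == "]" && !first) break
        first <- FALSE
        if (chars[j] == "%") {
          if (j == n) stop("malformed pattern: ends with '%'", call. = FALSE)
          set_items[[length(set_items) + 1L]] <-
            list(type = "class", class = chars[j + 1L])
          j <- j + 2L
        } else if (j + 2L <= n && chars[j + 1L] == "-" &&
                   chars[j + 2L] != "]") {
          set_items[[length(set_items) + 1L]] <-
            list(type = "range", lo = chars[j], hi = chars[j + 2L])
          j <- j + 3L
        } else {
          set_items[[length(set_items) + 1L]] <-
            list(type = "lit", ch = chars[j])
          j <- j + 1L
        }
      }
      item <- list(type = "set", negate = negate, items = set_items)
      i <- j + 1L
    } else if (ch == ".") {
      item <- list(type = "any")
      i <- i + 1L
    } else {
      item <- list(type = "lit", ch = ch)
      i <- i + 1L
    }
    if (i <= n && chars[i] %in% c("*", "+", "-", "?")) {
      item$quant <- chars[i]
      i <- i + 1L
    } else {
      item$quant <- ""
    }
    items[[length(items) + 1L]] <- item
  }
  list(anchored_start = anchored_start, items = items)
}

class_match <- function(cls, ch) {
  res <- switch(tolower(cls),
    a = grepl("[A-Za-z]", ch),
    c = grepl("[[:cntrl:]]", ch),
    d = grepl("[0-9]", ch),
    l = grepl("[a-z]", ch),
    p = grepl("[[:punct:]]", ch),
    s = grepl("[ \t\n\r\f\v]", ch),
    u = grepl("[A-Z]", ch),
    w = grepl("[A-Za-z0-9]", ch),
    x = grepl("[0-9A-Fa-f]", ch),
    NULL)
  if (is.null(res)) return(ch == cls)      # %<punct>: literal escape
  if (cls %in% LETTERS) !res else res      # uppercase class = complement
}

single_match <- function(item, ch) {
  switch(item$type,
    any = TRUE,
    lit = ch == item$ch,
    class = class_match(item$class, ch),
    set = {
      hit <- FALSE
      for (si in item$items) {
        ok <- switch(si$type,
          lit = ch == si$ch,
          class = class_match(si$class, ch),
          range = ch >= si$lo && ch <= si$hi)
        if (ok) {
          hit <- TRUE
          break
        }
      }
      if (item$negate) !hit else hit
    },
    FALSE)
}

# Backtracking match of compiled items against chars starting at si
# (1-based). Returns the 1-based index one past the last consumed char,
# or -1L on failure.
match_here <- function(chars, si, items, ii) {
  n <- length(chars)
  if (ii > length(items)) return(si)
  item <- items[[ii]]
  if (item$type == "end")
    return(if (si == n + 1L) si else -1L)
  q <- item$quant
  if (q == "") {
    if (si <= n && single_match(item, chars[si]))
      return(match_here(chars, si + 1L, items, ii + 1L))
    return(-1L)
  }
  if (q == "?") {
    if (si <= n && single_match(item, chars[si])) {
      r <- match_here(chars, si + 1L, items, ii + 1L)
      if (r >= 0L) return(r)
    }
    return(match_here(chars, si, items, ii + 1L))
  }
  if (q == "-") {             # lazy: shortest expansion first
    k <- si
    repeat {
      r <- match_here(chars, k, items, ii + 1L)
      if (r >= 0L) return(r)
      if (k <= n && single_match(item, chars[k])) k <- k + 1L
      else return(-1L)
    }
  }
  # greedy * and +
  maxk <- si
  while (maxk <= n && single_match(item, chars[maxk])) maxk <- maxk + 1L
  mink <- if (q == "+") si + 1L else si
  k <- maxk
  while (k >= mink) {
    r <- match_here(chars, k, items, ii + 1L)
    if (r >= 0L) return(r)
    k <- k - 1L
  }
  -1L
}

#' Match a Lua-style pattern against a string
#'
#' Finds the leftmost match of `pattern` in `s` using the dialect's pattern
#' syntax: `.` matches any character, `%d` and friends are character
#' classes (uppercase = complement), `[...]` sets with ranges and `^`
#' negation, quantifiers `*`, `+`, `-` (lazy), `?`, and the anchors `^`
#' (pattern start) and `$` (pattern end).
#'
#' @param s subject string.
#' @param pattern pattern text.
#' @param init 1-based position to start searching from.
#' @return Integer vector `c(start, end)` (1-based, inclusive; `end ==
#'   start - 1` for an empty match) or `NULL` when there is no match.
#' @export
match_pattern <- function(s, pattern, init = 1L) {
  cp <- compile_pattern(pattern)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  starts <- if (cp$anchored_start) max(1L, init)
            else seq.int(max(1L, init), n + 1L)
  for (start in starts) {
    if (start > n + 1L) break
    r <- match_here(chars, start, cp$items, 1L)
    if (r >= 0L) return(c(start, r - 1L))
    if (cp$anchored_start) break
  }
  NULL
}

# ---- tokenizer -------------------------------------------------------------

LUA_KEYWORDS <- c("and", "break", "do", "else", "elseif", "end", "false",
                  "for", "function", "if", "in", "local", "nil", "not",
                  "or", "repeat", "return", "then", "true", "until", "while")

lua_tokenize <- function(src) {
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(
    type = type, value = value)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[ \t\r\n]", ch)) {
      i <- i + 1L
    } else if (ch == "-" && i < n && chars[i + 1L] == "-") {
      # comment to end of line (long comments not supported)
      while (i <= n && chars[i] != "\n") i <- i + 1L
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      if (word %in% LUA_KEYWORDS) push("kw", word) else push("name", word)
      i <- j
    } else if (grepl("[0-9]", ch) ||
               (ch == "." && i < n && grepl("[0-9]", chars[i + 1L]))) {
      j <- i
      while (j <= n && grepl("[0-9.eExXa-fA-F+-]", chars[j])) {
        # stop '+'/'-' unless directly after an exponent marker
        if (chars[j] %in% c("+", "-") &&
            !(j > i && chars[j - 1L] %in% c("e", "E"))) break
        j <- j + 1L
      }
      num <- paste(chars[i:(j - 1L)], collapse = "")
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val)) stop("malformed number: ", num, call. = FALSE)
      push("number", val)
      i <- j
    } else if (ch %in% c("\"", "'")) {
      quote_ch <- ch
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != quote_ch) {
        if (chars[j] == "\\" && j < n) {
          esc <- chars[j + 1L]
          buf <- c(buf, switch(esc, n = "\n", t = "\t", r = "\r",
                               "\\" = "\\", "\"" = "\"", "'" = "'", esc))
          j <- j + 2L
        } else {
          buf <- c(buf, chars[j])
          j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string literal", call. = FALSE)
      push("string", paste(buf, collapse = ""))
      i <- j + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("==", "~=", "<=", ">=", "..")) {
        push("op", two)
        i <- i + 2L
      } else if (ch %in% c("+", "-", "*", "/", "%", "^", "#", "<", ">",
                           "=", "(", ")", "{", "}", "[", "]", ";", ":",
                           ",", ".")) {
        push("op", ch)
        i <- i + 1L
      } else {
        stop("unexpected character in script: '", ch, "'", call. = FALSE)
      }
    }
  }
  push("eof", "")
  toks
}

# ---- parser ----------------------------------------------------------------

lua_parse <- function(src) {
  toks <- lua_tokenize(src)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() {
    t <- toks[[pos]]
    pos <<- pos + 1L
    t
  }
  check <- function(type, value = NULL) {
    t <- peek()
    t$type == type && (is.null(value) || t$value == value)
  }
  expect <- function(type, value = NULL) {
    if (!check(type, value))
      stop(sprintf("script parse error: expected %s near '%s'",
                   value %||% type, peek()$value), call. = FALSE)
    advance()
  }
  accept <- function(type, value = NULL) {
    if (check(type, value)) {
      advance()
      TRUE
    } else FALSE
  }

  block_end <- function()
    check("eof") || check("kw", "end") || check("kw", "else") ||
      check("kw", "elseif") || check("kw", "until")

  parse_block <- function() {
    stats <- list()
    while (!block_end()) {
      if (accept("op", ";")) next
      s <- parse_statement()
      stats[[length(stats) + 1L]] <- s
      if (s$type == "return") break
    }
    list(type = "block", stats = stats)
  }

  parse_statement <- function() {
    if (accept("kw", "local")) {
      names <- expect("name")$value
      while (accept("op", ",")) names <- c(names, expect("name")$value)
      exprs <- list()
      if (accept("op", "=")) exprs <- parse_explist()
      return(list(type = "local", names = names, exprs = exprs))
    }
    if (accept("kw", "if")) return(parse_if())
    if (accept("kw", "while")) {
      cond <- parse_expr()
      expect("kw", "do")
      body <- parse_block()
      expect("kw", "end")
      return(list(type = "while", cond = cond, body = body))
    }
    if (accept("kw", "return")) {
      exprs <- if (!block_end() && !check("op", ";")) parse_explist()
               else list()
      return(list(type = "return", exprs = exprs))
    }
    if (accept("kw", "function")) {
      # function Name { '.' Name } funcbody  -- assigns globally
      target <- list(type = "name", name = expect("name")$value)
      while (accept("op", ".")) {
        target <- list(type = "index", obj = target,
                       key = list(type = "string", value = expect("name")$value))
      }
      fn <- parse_funcbody()
      return(list(type = "assign", targets = list(target), exprs = list(fn)))
    }
    if (accept("kw", "do")) {
      body <- parse_block()
      expect("kw", "end")
      return(list(type = "do", body = body))
    }
    # expression statement: call, or assignment
    e <- parse_suffixed()
    if (check("op", "=") || check("op", ",")) {
      targets <- list(e)
      while (accept("op", ",")) targets[[length(targets) + 1L]] <-
        parse_suffixed()
      expect("op", "=")
      exprs <- parse_explist()
      return(list(type = "assign", targets = targets, exprs = exprs))
    }
    if (!e$type %in% c("call", "method"))
      stop("script parse error: unexpected expression statement",
           call. = FALSE)
    list(type = "exprstat", expr = e)
  }

  parse_if <- function() {
    cond <- parse_expr()
    expect("kw", "then")
    then_blk <- parse_block()
    if (accept("kw", "elseif")) {
      else_blk <- list(type = "block", stats = list(parse_if()))
      return(list(type = "if", cond = cond, then = then_blk,
                  else_ = else_blk))
    }
    else_blk <- NULL
    if (accept("kw", "else")) else_blk <- parse_block()
    expect("kw", "end")
    list(type = "if", cond = cond, then = then_blk, else_ = else_blk)
  }

  parse_funcbody <- function() {
    expect("op", "(")
    params <- character(0)
    if (!check("op", ")")) {
      params <- expect("name")$value
      while (accept("op", ",")) params <- c(params, expect("name")$value)
    }
    expect("op", ")")
    body <- parse_block()
    expect("kw", "end")
    list(type = "function", params = params, body = body)
  }

  parse_explist <- function() {
    out <- list(parse_expr())
    while (accept("op", ",")) out[[length(out) + 1L]] <- parse_expr()
    out
  }

  # precedence climbing
  parse_expr <- function() parse_or()
  parse_or <- function() {
    left <- parse_and()
    while (accept("kw", "or"))
      left <- list(type = "or", left = left, right = parse_and())
    left
  }
  parse_and <- function() {
    left <- parse_cmp()
    while (accept("kw", "and"))
      left <- list(type = "and", left = left, right = parse_cmp())
    left
  }
  parse_cmp <- function() {
    left <- parse_concat()
    while (check("op", "==") || check("op", "~=") || check("op", "<") ||
           check("op", ">") || check("op", "<=") || check("op", ">=")) {
      op <- advance()$value
      left <- list(type = "binop", op = op, left = left,
                   right = parse_concat())
    }
    left
  }
  parse_concat <- function() {
    left <- parse_add()
    if (check("op", "..")) {
      advance()
      return(list(type = "binop", op = "..", left = left,
                  right = parse_concat()))   # right associative
    }
    left
  }
  parse_add <- function() {
    left <- parse_mul()
    while (check("op", "+") || check("op", "-")) {
      op <- advance()$value
      left <- list(type = "binop", op = op, left = left, right = parse_mul())
    }
    left
  }
  parse_mul <- function() {
    left <- parse_unary()
    while (check("op", "*") || check("op", "/") || check("op", "%")) {
      op <- advance()$value
      left <- list(type = "binop", op = op, left = left,
                   right = parse_unary())
    }
    left
  }
  parse_unary <- function() {
    if (accept("kw", "not"))
      return(list(type = "not", expr = parse_unary()))
    if (accept("op", "-"))
      return(list(type = "neg", expr = parse_unary()))
    if (accept("op", "#"))
      return(list(type = "len", expr = parse_unary()))
    parse_suffixed()
  }

  parse_primary <- function() {
    t <- peek()
    if (t$type == "number") {
      advance()
      return(list(type = "number", value = t$value))
    }
    if (t$type == "string") {
      advance()
      return(list(type = "string", value = t$value))
    }
    if (accept("kw", "nil")) return(list(type = "nil"))
    if (accept("kw", "true")) return(list(type = "true"))
    if (accept("kw", "false")) return(list(type = "false"))
    if (accept("kw", "function")) return(parse_funcbody())
    if (accept("op", "(")) {
      e <- parse_expr()
      expect("op", ")")
      return(list(type = "paren", expr = e))
    }
    if (t$type == "name") {
      advance()
      return(list(type = "name", name = t$value))
    }
    stop("script parse error: unexpected '", t$value, "'", call. = FALSE)
  }

  parse_args <- function() {
    if (peek()$type == "string") {
      s <- advance()
      return(list(list(type = "string", value = s$value)))
    }
    expect("op", "(")
    args <- list()
    if (!check("op", ")")) args <- parse_explist()
    expect("op", ")")
    args
  }

  parse_suffixed <- function() {
    e <- parse_primary()
    repeat {
      if (accept("op", ".")) {
        e <- list(type = "index", obj = e,
                  key = list(type = "string", value = expect("name")$value))
      } else if (accept("op", "[")) {
        k <- parse_expr()
        expect("op", "]")
        e <- list(type = "index", obj = e, key = k)
      } else if (accept("op", ":")) {
        m <- expect("name")$value
        args <- parse_args()
        e <- list(type = "method", obj = e, name = m, args = args)
      } else if (check("op", "(") || peek()$type == "string") {
        args <- parse_args()
        e <- list(type = "call", fn = e, args = args)
      } else break
    }
    e
  }

  blk <- parse_block()
  expect("eof")
  blk
}

# ---- evaluator -------------------------------------------------------------

# values: NULL = nil, logical, numeric, character, lua_function (closure),
# lua_builtin (R function taking a list of values, returning a list of
# values), environment = table

lua_truthy <- function(v) !is.null(v) && !identical(v, FALSE)

lua_type_name <- function(v) {
  if (is.null(v)) "nil"
  else if (is.logical(v)) "boolean"
  else if (is.numeric(v)) "number"
  else if (is.character(v)) "string"
  else if (is.environment(v)) "table"
  else "function"
}

lua_tostring <- function(v) {
  if (is.null(v)) return("nil")
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.numeric(v)) {
    if (is.finite(v) && v == floor(v) && abs(v) < 1e15)
      return(sprintf("%.0f", v))
    return(as.character(v))
  }
  if (is.character(v)) return(v)
  paste0("<", lua_type_name(v), ">")
}

lua_tonumber <- function(v) {
  if (is.numeric(v)) return(v)
  if (is.character(v)) {
    x <- suppressWarnings(as.numeric(v))
    return(if (is.na(x)) NULL else x)
  }
  NULL
}

lua_check_string <- function(v, fname) {
  if (is.character(v)) return(v)
  if (is.numeric(v)) return(lua_tostring(v))
  stop(sprintf("script error: bad argument to '%s' (string expected, got %s)",
               fname, lua_type_name(v)), call. = FALSE)
}

# Lua string.sub index normalisation: 0 counts as 1, negatives from the end
lua_sub_index <- function(i, len, default) {
  if (is.null(i)) return(default)
  i <- floor(i)
  if (i < 0) i <- max(len + i + 1, 1)
  else if (i == 0) i <- 1
  i
}

lua_string_lib <- function() {
  lib <- new.env(parent = emptyenv())
  lib$len <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "len")
    list(nchar(s))
  }
  lib$sub <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "sub")
    len <- nchar(s)
    i <- lua_sub_index(lua_tonumber(args[[2]] %||% NULL), len, 1)
    j <- lua_sub_index_end(lua_tonumber(if (length(args) >= 3) args[[3]]),
                           len)
    if (i > j) return(list(""))
    list(substr(s, i, min(j, len)))
  }
  lib$upper <- function(args)
    list(toupper(lua_check_string(args[[1]] %||% NULL, "upper")))
  lib$lower <- function(args)
    list(tolower(lua_check_string(args[[1]] %||% NULL, "lower")))
  lib$rep <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "rep")
    n <- lua_tonumber(args[[2]] %||% NULL) %||% 0
    list(paste(rep(s, max(0, floor(n))), collapse = ""))
  }
  lib$reverse <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "reverse")
    list(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }
  lib$find <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "find")
    p <- lua_check_string(args[[2]] %||% NULL, "find")
    init <- lua_tonumber(if (length(args) >= 3) args[[3]]) %||% 1
    span <- match_pattern(s, p, init = as.integer(init))
    if (is.null(span)) list(NULL) else list(span[1], span[2])
  }
  lib$match <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "match")
    p <- lua_check_string(args[[2]] %||% NULL, "match")
    init <- lua_tonumber(if (length(args) >= 3) args[[3]]) %||% 1
    span <- match_pattern(s, p, init = as.integer(init))
    if (is.null(span)) list(NULL)
    else list(substr(s, span[1], span[2]))
  }
  lib$gsub <- function(args) {
    s <- lua_check_string(args[[1]] %||% NULL, "gsub")
    p <- lua_check_string(args[[2]] %||% NULL, "gsub")
    repl <- lua_check_string(args[[3]] %||% NULL, "gsub")
    count <- 0L
    out <- ""
    pos <- 1L
    len <- nchar(s)
    repeat {
      span <- match_pattern(s, p, init = pos)
      if (is.null(span)) break
      out <- paste0(out, substr(s, pos, span[1] - 1L), repl)
      count <- count + 1L
      pos <- if (span[2] >= span[1]) span[2] + 1L
             else {   # empty match: copy one char and step
        if (span[1] <= len) out <- paste0(out, substr(s, span[1], span[1]))
        span[1] + 1L
      }
      if (pos > len + 1L) break
    }
    out <- paste0(out, substr(s, pos, len))
    list(out, count)
  }
  lib
}

lua_sub_index_end <- function(j, len) {
  if (is.null(j)) return(len)
  j <- floor(j)
  if (j < 0) j <- len + j + 1
  j
}

lua_globals <- function(state) {
  g <- new.env(parent = emptyenv())
  g$string <- lua_string_lib()
  g$tostring <- function(args) list(lua_tostring(args[[1]] %||% NULL))
  g$tonumber <- function(args) list(lua_tonumber(args[[1]] %||% NULL))
  g$type <- function(args) list(lua_type_name(args[[1]] %||% NULL))
  g$error <- function(args)
    stop("script error: ", lua_tostring(args[[1]] %||% NULL), call. = FALSE)
  g$assert <- function(args) {
    if (!lua_truthy(args[[1]] %||% NULL))
      stop("script error: assertion failed", call. = FALSE)
    args
  }
  g
}

lua_new_state <- function(step_limit = 1e6, time_limit = 5) {
  state <- new.env(parent = emptyenv())
  state$steps <- 0L
  state$step_limit <- step_limit
  state$deadline <- Sys.time() + time_limit
  state$globals <- lua_globals(state)
  state
}

lua_tick <- function(state) {
  state$steps <- state$steps + 1L
  if (state$steps > state$step_limit)
    stop("script error: step limit exceeded", call. = FALSE)
  if (state$steps %% 1024L == 0L && Sys.time() > state$deadline)
    stop("script error: time limit exceeded", call. = FALSE)
}

lua_frame <- function(parent_frame) {
  f <- new.env(parent = emptyenv())
  f$vars <- new.env(parent = emptyenv())
  f$parent <- parent_frame
  f
}

lua_lookup <- function(frame, state, name) {
  f <- frame
  while (!is.null(f)) {
    if (!is.null(f$vars[[name]]) || exists(name, envir = f$vars,
                                           inherits = FALSE))
      return(f$vars[[name]])
    f <- f$parent
  }
  state$globals[[name]]
}

lua_set <- function(frame, state, name, value) {
  f <- frame
  while (!is.null(f)) {
    if (exists(name, envir = f$vars, inherits = FALSE)) {
      assign(name, value, envir = f$vars)
      return(invisible())
    }
    f <- f$parent
  }
  assign(name, value, envir = state$globals)
  invisible()
}

# control flow: return is signalled via a condition carrying the values
lua_return <- function(values)
  stop(structure(class = c("lua_return", "condition"),
                 list(message = "", call = NULL, values = values)))

# evaluate an expression list with Lua adjustment: every expression but the
# last truncates to one value; the last expands all of its values
lua_eval_explist <- function(exprs, frame, state) {
  vals <- list()
  nn <- length(exprs)
  if (nn == 0L) return(vals)
  for (k in seq_len(nn)) {
    vs <- lua_eval_multi(exprs[[k]], frame, state)
    if (k < nn) vals[[k]] <- if (length(vs)) vs[[1]] else NULL
    else vals <- c(vals, if (length(vs)) vs else list(NULL))
  }
  vals
}

lua_eval1 <- function(expr, frame, state) {
  vs <- lua_eval_multi(expr, frame, state)
  if (length(vs)) vs[[1]] else NULL
}

lua_call_value <- function(fn, args, state, what = "value") {
  if (is.function(fn)) return(fn(args))      # builtin
  if (is.list(fn) && identical(fn$tag, "lua_closure")) {
    frame <- lua_frame(fn$env)
    for (k in seq_along(fn$params)) {
      assign(fn$params[k], if (k <= length(args)) args[[k]] else NULL,
             envir = frame$vars)
    }
    res <- tryCatch({
      lua_exec_block(fn$body, frame, state)
      list()
    }, lua_return = function(c) c$values)
    return(res)
  }
  stop(sprintf("script error: attempt to call a %s value",
               lua_type_name(fn)), call. = FALSE)
}

lua_eval_multi <- function(expr, frame, state) {
  lua_tick(state)
  switch(expr$type,
    number = list(expr$value),
    string = list(expr$value),
    nil = list(NULL),
    true = list(TRUE),
    false = list(FALSE),
    paren = list(lua_eval1(expr$expr, frame, state)),
    name = list(lua_lookup(frame, state, expr$name)),
    "function" = list(list(tag = "lua_closure", params = expr$params,
                           body = expr$body, env = frame)),
    index = {
      obj <- lua_eval1(expr$obj, frame, state)
      key <- lua_eval1(expr$key, frame, state)
      if (is.null(obj)) {
        nm <- if (expr$obj$type == "name") sprintf(" (global '%s')",
                                                   expr$obj$name) else ""
        stop("script error: attempt to index a nil value", nm,
             call. = FALSE)
      }
      if (!is.environment(obj))
        stop("script error: attempt to index a ",
             lua_type_name(obj), " value", call. = FALSE)
      list(obj[[lua_tostring(key)]])
    },
    call = {
      fn <- lua_eval1(expr$fn, frame, state)
      args <- lua_eval_explist(expr$args, frame, state)
      lua_call_value(fn, args, state)
    },
    method = {
      obj <- lua_eval1(expr$obj, frame, state)
      args <- lua_eval_explist(expr$args, frame, state)
      if (is.character(obj)) {
        # string method sugar: s:find(p) -> string.find(s, p)
        lib <- state$globals$string
        fn <- lib[[expr$name]]
        if (is.null(fn))
          stop("script error: unknown string method '", expr$name, "'",
               call. = FALSE)
        lua_call_value(fn, c(list(obj), args), state)
      } else if (is.environment(obj)) {
        fn <- obj[[expr$name]]
        lua_call_value(fn, c(list(obj), args), state)
      } else {
        stop("script error: attempt to index a ", lua_type_name(obj),
             " value", call. = FALSE)
      }
    },
    "and" = {
      l <- lua_eval1(expr$left, frame, state)
      if (!lua_truthy(l)) list(l)
      else list(lua_eval1(expr$right, frame, state))
    },
    "or" = {
      l <- lua_eval1(expr$left, frame, state)
      if (lua_truthy(l)) list(l)
      else list(lua_eval1(expr$right, frame, state))
    },
    "not" = list(!lua_truthy(lua_eval1(expr$expr, frame, state))),
    neg = {
      v <- lua_tonumber(lua_eval1(expr$expr, frame, state))
      if (is.null(v))
        stop("script error: attempt to perform arithmetic on a non-number",
             call. = FALSE)
      list(-v)
    },
    len = {
      v <- lua_eval1(expr$expr, frame, state)
      if (!is.character(v))
        stop("script error: attempt to get length of a ",
             lua_type_name(v), " value", call. = FALSE)
      list(nchar(v))
    },
    binop = {
      l <- lua_eval1(expr$left, frame, state)
      r <- lua_eval1(expr$right, frame, state)
      list(lua_binop(expr$op, l, r))
    },
    stop("script error: cannot evaluate expression of type ", expr$type,
         call. = FALSE)
  )
}

lua_binop <- function(op, l, r) {
  if (op == "..") {
    ok <- function(v) is.character(v) || is.numeric(v)
    if (!ok(l) || !ok(r))
      stop("script error: attempt to concatenate a ",
           lua_type_name(if (!ok(l)) l else r), " value", call. = FALSE)
    return(paste0(lua_tostring(l), lua_tostring(r)))
  }
  if (op %in% c("==", "~=")) {
    eq <- identical(lua_type_name(l), lua_type_name(r)) && identical(l, r)
    return(if (op == "==") eq else !eq)
  }
  if (op %in% c("<", ">", "<=", ">=")) {
    if (is.character(l) && is.character(r)) {
      # total order on strings (C collation via explicit comparison)
      return(switch(op, "<" = l < r, ">" = l > r,
                    "<=" = l <= r, ">=" = l >= r))
    }
    ln <- lua_tonumber(l)
    rn <- lua_tonumber(r)
    if (is.numeric(l) && is.numeric(r))
      return(switch(op, "<" = ln < rn, ">" = ln > rn,
                    "<=" = ln <= rn, ">=" = ln >= rn))
    stop("script error: attempt to compare ", lua_type_name(l), " with ",
         lua_type_name(r), call. = FALSE)
  }
  # arithmetic
  ln <- lua_tonumber(l)
  rn <- lua_tonumber(r)
  if (is.null(ln) || is.null(rn))
    stop("script error: attempt to perform arithmetic on a ",
         lua_type_name(if (is.null(lua_tonumber(l))) l else r), " value",
         call. = FALSE)
  switch(op,
    "+" = ln + rn,
    "-" = ln - rn,
    "*" = ln * rn,
    "/" = ln / rn,
    "%" = ln - floor(ln / rn) * rn,
    "^" = ln^rn,
    stop("script error: unknown operator ", op, call. = FALSE))
}

lua_exec_block <- function(block, frame, state) {
  for (s in block$stats) lua_exec_stat(s, frame, state)
  invisible()
}

lua_exec_stat <- function(stat, frame, state) {
  lua_tick(state)
  switch(stat$type,
    local = {
      vals <- lua_eval_explist(stat$exprs, frame, state)
      for (k in seq_along(stat$names))
        assign(stat$names[k], if (k <= length(vals)) vals[[k]] else NULL,
               envir = frame$vars)
    },
    assign = {
      vals <- lua_eval_explist(stat$exprs, frame, state)
      for (k in seq_along(stat$targets)) {
        v <- if (k <= length(vals)) vals[[k]] else NULL
        tgt <- stat$targets[[k]]
        if (tgt$type == "name") {
          lua_set(frame, state, tgt$name, v)
        } else if (tgt$type == "index") {
          obj <- lua_eval1(tgt$obj, frame, state)
          if (!is.environment(obj))
            stop("script error: attempt to index a ",
                 lua_type_name(obj), " value", call. = FALSE)
          key <- lua_tostring(lua_eval1(tgt$key, frame, state))
          assign(key, v, envir = obj)
        } else stop("script error: invalid assignment target",
                    call. = FALSE)
      }
    },
    "if" = {
      if (lua_truthy(lua_eval1(stat$cond, frame, state)))
        lua_exec_block(stat$then, lua_frame(frame), state)
      else if (!is.null(stat$else_))
        lua_exec_block(stat$else_, lua_frame(frame), state)
    },
    "while" = {
      repeat {
        if (!lua_truthy(lua_eval1(stat$cond, frame, state))) break
        lua_exec_block(stat$body, lua_frame(frame), state)
      }
    },
    "return" = lua_return(lua_eval_explist(stat$exprs, frame, state)),
    "do" = lua_exec_block(stat$body, lua_frame(frame), state),
    exprstat = invisible(lua_eval_multi(stat$expr, frame, state)),
    stop("script error: cannot execute statement of type ", stat$type,
         call. = FALSE)
  )
  invisible()
}

# Run a script chunk, returning the interpreter state (globals populated)
lua_run <- function(src, state = lua_new_state()) {
  ast <- lua_parse(src)
  root <- lua_frame(NULL)
  tryCatch(lua_exec_block(ast, root, state),
           lua_return = function(c) invisible())
  state
}
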