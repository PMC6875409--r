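test_that("widget mapping is total with the text-input fallback", {
  expect_identical(widget_for("boolean"), "checkbox")
  expect_identical(widget_for("file"), "filedialog")
  expect_identical(widget_for("directory"), "filedialog")
  expect_identical(widget_for("choice"), "combobox")
  expect_identical(widget_for("integer"), "textinput")
  expect_identical(widget_for("float"), "textinput")
  expect_identical(widget_for("string"), "textinput")
  expect_identical(widget_for("unknown"), "textinput")
  expect_identical(widget_for("some-future-type"), "textinput")
})

test_that("generated templates assemble flags, booleans and positionals", {
  echo <- cli_spec("echo_msg", "echo",
                   inputs = list(list(name = "msg", value_type = "string",
                                      required = TRUE, position = 1)))
  t <- from_cli_spec(echo)
  expect_length(Filter(function(d) d$severity == "error",
                       validate_template(t)), 0)
  inv <- assemble_invocation(t, collect_bindings(t$window,
                                                 list(msg = "hi")))[[1]]
  expect_identical(inv$program, "echo")
  expect_identical(inv$argument_text, "hi")

  verbose <- cli_spec("vtool", "vtool",
                      inputs = list(list(name = "verbose",
                                         value_type = "boolean",
                                         flag = "--verbose")))
  tv <- from_cli_spec(verbose)
  on_ <- assemble_invocation(tv, collect_bindings(tv$window,
                                                  list(verbose = TRUE)))[[1]]
  off <- assemble_invocation(tv, collect_bindings(tv$window,
                                                  list(verbose = FALSE)))[[1]]
  expect_match(on_$argument_text, "--verbose", fixed = TRUE)
  expect_false(grepl("--verbose", off$argument_text, fixed = TRUE))

  # optional flagged input leaves no trace while empty
  opt <- cli_spec("otool", "otool",
                  inputs = list(list(name = "th", value_type = "integer",
                                     flag = "-t", required = FALSE)))
  to <- from_cli_spec(opt)
  with_val <- assemble_invocation(to, collect_bindings(to$window,
                                                       list(th = "5")))[[1]]
  without <- assemble_invocation(to, collect_bindings(to$window,
                                                      list(th = "")))[[1]]
  expect_identical(with_val$argument_text, "-t 5")
  expect_identical(without$argument_text, "")
})

test_that("subcommands gate their argument groups through the combobox", {
  spec <- cli_spec("multi", "multi",
                   subcommands = list(
                     cli_spec("align", "align",
                              inputs = list(list(name = "ref",
                                                 value_type = "file",
                                                 flag = "-r",
                                                 required = TRUE))),
                     cli_spec("index", "index",
                              inputs = list(list(name = "k",
                                                 value_type = "integer",
                                                 flag = "-k",
                                                 required = TRUE)))))
  t <- from_cli_spec(spec)
  expect_length(Filter(function(d) d$severity == "error",
                       validate_template(t)), 0)
  b <- collect_bindings(t$window, list(subcommand = "align",
                                       align_ref = "g.fa", index_k = "21"))
  inv <- assemble_invocation(t, b)[[1]]
  expect_match(inv$argument_text, "^align ")
  expect_match(inv$argument_text, "-r g.fa", fixed = TRUE)
  expect_false(grepl("-k 21", inv$argument_text, fixed = TRUE))
})

test_that("generator totality holds over random specifications", {
  set.seed(1009)
  for (i in seq_len(50)) {
    spec <- random_cli_spec()
    t <- from_cli_spec(spec)
    errs <- Filter(function(d) d$severity == "error", validate_template(t))
    expect_length(errs, 0)
    # exactly one bindable widget per input
    keys <- form_schema_binding_keys(to_form_schema(t))
    expect_length(keys, length(spec$inputs))
    # unknown types became text inputs
    schema_kinds <- vapply(
      Filter(function(e) !is.null(e$id), to_form_schema(t)$entries),
      function(e) e$kind, character(1))
    for (k in seq_along(spec$inputs))
      if (spec$inputs[[k]]$value_type == "unknown")
        expect_identical(
          schema_kinds[match(spec$inputs[[k]]$name, keys)], "input")
    # assembly mentions every required flag
    inv <- assemble_invocation(t, all_bindings_for_spec(spec, t))[[1]]
    for (inp in spec$inputs)
      if (inp$required && !is.null(inp$flag) &&
          inp$value_type != "boolean")
        expect_match(inv$argument_text, inp$flag, fixed = TRUE)
  }
})

test_that("CWL CommandLineTool documents convert to CLI specs", {
  wc <- from_cwl(fixture_path("wc-tool.cwl"))
  expect_identical(wc$base_command, "wc")
  expect_length(wc$inputs, 1)
  expect_identical(wc$inputs[[1]]$flag, "-c")
  expect_identical(wc$inputs[[1]]$value_type, "file")

  trim <- from_cwl(fixture_path("trim-tool.cwl"))
  expect_identical(trim$base_command, c("trimtool", "run"))
  types <- vapply(trim$inputs, function(i) i$value_type, character(1))
  expect_identical(types, c("file", "integer", "choice", "boolean",
                            "string"))
  req <- vapply(trim$inputs, function(i) i$required, logical(1))
  expect_identical(req, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(trim$inputs[[3]]$options, list("fast", "sensitive"))
  expect_identical(trim$inputs[[5]]$position, 1L)

  # record type falls back to unknown -> text input downstream
  rec <- from_cwl(fixture_path("record-tool.cwl"))
  expect_identical(rec$inputs[[1]]$value_type, "unknown")
  t <- from_cli_spec(rec)
  schema <- to_form_schema(t)
  entry <- Filter(function(e) identical(e$id, "settings"), schema$entries)
  expect_identical(entry[[1]]$kind, "input")

  expect_error(from_cwl("class: Workflow\ncwlVersion: v1.0\n"),
               "unsupported document class")
  expect_error(from_cwl("cwlVersion: v1.0\n"), "missing 'class'")
  noin <- from_cwl("class: CommandLineTool\ncwlVersion: v1.0\nbaseCommand: ls\n")
  expect_length(noin$inputs, 0)
  warns <- attr(noin, "warnings")
  expect_true(any(vapply(warns, function(w) grepl("no inputs", w$message),
                         logical(1))))
})

test_that("CWL conversion composes with the template generator", {
  for (f in c("wc-tool.cwl", "trim-tool.cwl", "record-tool.cwl")) {
    spec <- from_cwl(fixture_path(f))
    t <- from_cli_spec(spec)
    errs <- Filter(function(d) d$severity == "error", validate_template(t))
    expect_length(errs, 0)
    expect_length(form_schema_binding_keys(to_form_schema(t)),
                  length(spec$inputs))
    inv <- assemble_invocation(t, all_bindings_for_spec(spec, t))[[1]]
    for (inp in spec$inputs)
      if (inp$required && !is.null(inp$flag) &&
          inp$value_type != "boolean")
        expect_match(inv$argument_text, inp$flag, fixed = TRUE)
  }
})
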