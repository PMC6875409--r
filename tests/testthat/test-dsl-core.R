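test_that("parsing preserves structure and document order", {
  t <- parse_template(fixture_path("minimal.xml"))
  expect_s3_class(t, "forge_template")
  kinds <- vapply(t$window, function(e) e$kind, character(1))
  expect_equal(kinds, c("filedialog", "action", "streambox"))
  expect_length(t$execution, 1)
  expect_equal(t$execution[[1]]$kind, "execute")

  t2 <- stream_template()
  kinds2 <- vapply(t2$window, function(e) e$kind, character(1))
  expect_equal(kinds2, c("label", "filedialog", "group", "action",
                         "streambox"))
  grp <- t2$window[[3]]
  expect_true(grp$checkable)
  expect_equal(grp$children[[1]]$kind, "filedialog")
  expect_equal(grp$children[[1]]$mode, "save")
  expect_equal(t2$execution[[1]]$kind, "if")
  expect_equal(t2$execution[[2]]$program, "sh")
})

test_that("malformed and unknown input is rejected loudly", {
  expect_error(parse_template("<template><window>"), "parse error")
  expect_error(parse_template(
    "<template id=\"t\"><window><widget id=\"x\"/></window><execution><execute program=\"a\"/></execution></template>"),
    "unknown window element <widget>")
  expect_error(parse_template(
    "<template id=\"t\"><window><action/></window><execution><frobnicate/></execution></template>"),
    "unknown execution node <frobnicate>")
  expect_error(parse_template("<form><window/></form>"), "root must be")
})

test_that("unknown attributes are warnings, not errors", {
  t <- parse_template(
    "<template id=\"t\"><window><input id=\"a\" color=\"red\"/><action/></window><execution><execute program=\"x\"><param>${a}</param></execute></execution></template>")
  warns <- attr(t, "parse_warnings")
  expect_length(warns, 1)
  expect_equal(warns[[1]]$severity, "warning")
  expect_match(warns[[1]]$message, "color")
  diags <- validate_template(t)
  expect_false(any(vapply(diags, function(d) d$severity == "error",
                          logical(1))))
})

test_that("validation flags duplicates, unresolved refs and cycles", {
  expect_length(validate_template(stream_template()), 0)

  dup <- parse_template(
    "<template id=\"t\"><window><input id=\"input\"/><input id=\"input\"/><action/></window><execution><execute program=\"x\"><param>${input}</param></execute></execution></template>")
  errs <- Filter(function(d) d$severity == "error", validate_template(dup))
  expect_length(errs, 1)
  expect_equal(errs[[1]]$location, "input")
  expect_match(errs[[1]]$message, "duplicate")

  unresolved <- parse_template(
    "<template id=\"t\"><window><action/></window><execution><execute program=\"x\"><param>${ghost}</param></execute></execution></template>")
  errs <- Filter(function(d) d$severity == "error",
                 validate_template(unresolved))
  expect_length(errs, 1)
  expect_match(errs[[1]]$message, "\\$\\{ghost\\}")

  cyc <- parse_template(
    "<template id=\"t\"><window><action/></window><execution><add id=\"A\">${B}</add><add id=\"B\">${A}</add><execute program=\"x\"><param>${A}</param></execute></execution></template>")
  errs <- Filter(function(d) d$severity == "error", validate_template(cyc))
  expect_length(errs, 1)
  expect_match(errs[[1]]$message, "cycle")
})

test_that("serialize/parse round-trips all fixtures structurally", {
  for (f in fixture_template_files()) {
    t <- parse_template(f)
    t2 <- parse_template(serialize_template(t))
    expect_true(template_equal(t, t2), label = basename(f))
    # serialized output re-validates with no errors
    errs <- Filter(function(d) d$severity == "error", validate_template(t2))
    expect_length(errs, 0)
    # idempotence of the canonical form
    expect_identical(serialize_template(t2), serialize_template(t))
  }
})

test_that("form schema mirrors the window tree and its binding keys", {
  t <- stream_template()
  schema <- to_form_schema(t)
  expect_setequal(form_schema_binding_keys(schema),
                  c("input", "os", "outfile"))
  # document order
  expect_equal(form_schema_binding_keys(schema),
               c("input", "os", "outfile"))
  grp <- schema$entries[[3]]
  expect_true(grp$checkable)
  expect_true(grp$children[[1]]$pathTyped)
  # labels and stream boxes contribute no keys
  labels_only <- parse_template(
    "<template id=\"t\"><window><label>a</label><label>b</label><action/><streambox/></window><execution><execute program=\"x\"/></execution></template>")
  expect_length(form_schema_binding_keys(to_form_schema(labels_only)), 0)
  # schema completeness: keys equal the referenceable window ids
  for (f in fixture_template_files()) {
    tt <- parse_template(f)
    expect_setequal(form_schema_binding_keys(to_form_schema(tt)),
                    cmdforge:::bindable_ids(tt$window))
  }
  expect_match(as.character(form_schema_json(schema)), "\"pathTyped\": true")
})
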