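test_that("register/list/search/remove keep the manifest consistent", {
  st <- store_open(tempfile("store"))
  t <- stream_template()
  store_register(st, t)
  entries <- store_list(st)
  expect_identical(entries$id, "stream_example")
  # idempotent per id
  store_register(st, t)
  expect_identical(nrow(store_list(st)), 1L)

  m <- parse_template(fixture_path("minimal.xml"))
  store_register(st, m)
  expect_identical(nrow(store_list(st)), 2L)

  # case-insensitive substring search over name + description
  expect_identical(store_search(st, "STREAM")$id, "stream_example")
  expect_identical(store_search(st, "network listener")$id, "stream_example")
  expect_identical(nrow(store_search(st, "")), 2L)
  expect_identical(nrow(store_search(st, "zzz-nomatch")), 0L)

  store_remove(st, "minimal")
  expect_identical(store_list(st)$id, "stream_example")
  expect_error(store_remove(st, "minimal"), "no store entry")

  # loading re-parses the registered document
  expect_true(template_equal(store_load(st, "stream_example"), t))
  expect_error(store_register(st, parse_template(
    "<template id=\"bad\"><window><action/></window><execution><execute program=\"x\"><param>${ghost}</param></execute></execution></template>")),
    "invalid template")
})

test_that("saved runs reload and reassemble to the identical invocation", {
  st <- store_open(tempfile("store"))
  t <- stream_template()
  store_register(st, t)
  b <- collect_bindings(t$window, list(input = "inputFile", os = TRUE))
  save_filled(st, t, b, "worked example")
  invs <- reassemble_filled(st, "worked example")
  expect_identical(invs[[1]]$program, "sh")
  expect_identical(invs[[1]]$argument_text,
                   "-c \"cat inputFile | netcat 192.168.1.100 55025\"")
  # bindings map round-trips exactly
  run <- load_filled(st, "worked example")
  expect_identical(run$bindings$values, b$values)
  expect_setequal(run$bindings$path_typed, b$path_typed)
  expect_error(load_filled(st, "never saved"), "no saved run")
  expect_error(save_filled(st, parse_template(fixture_path("minimal.xml")),
                           b, "x"), "not registered")
})

test_that("reproducibility holds for random bindings over all fixtures", {
  set.seed(90125)
  st <- store_open(tempfile("store"))
  for (f in fixture_template_files()) {
    t <- parse_template(f)
    store_register(st, t)
    for (rep in 1:5) {
      raw <- list()
      for (id in form_schema_binding_keys(to_form_schema(t))) {
        el_kind <- vapply(cmdforge:::window_elements_flat(t$window),
                          function(e) identical(e$id, id), logical(1))
        el <- cmdforge:::window_elements_flat(t$window)[[which(el_kind)]]
        raw[[id]] <- if (el$kind == "checkbox" ||
                         (el$kind == "group" && isTRUE(el$checkable)))
          sample(c("TRUE", "FALSE"), 1)
        else if (el$kind == "combobox") sample(unlist(el$options), 1)
        else paste0(paste(sample(letters, 5), collapse = ""), ".1.ht2")
      }
      b <- collect_bindings(t$window, raw)
      direct <- assemble_invocation(t, b)
      label <- sprintf("%s rep %d", t$id, rep)
      save_filled(st, t, b, label)
      reloaded <- reassemble_filled(st, label)
      expect_identical(
        vapply(reloaded, function(i) i$argument_text, character(1)),
        vapply(direct, function(i) i$argument_text, character(1)),
        label = label)
    }
  }
})

test_that("secret-flagged values never reach the saved document", {
  st <- store_open(tempfile("store"))
  t <- parse_template(
    "<template id=\"auth\" title=\"Authenticated fetch\"><window><input id=\"user\"/><input id=\"token\" secret=\"true\"/><action/></window><execution><execute program=\"fetch\"><param>-u ${user} -t ${token}</param></execute></execution></template>")
  store_register(st, t)
  b <- collect_bindings(t$window, list(user = "luisa", token = "hunter2"))
  path <- save_filled(st, t, b, "auth run")
  saved_text <- paste(readLines(path), collapse = "\n")
  expect_false(grepl("hunter2", saved_text, fixed = TRUE))
  expect_match(saved_text, "luisa")
  # nothing anywhere under the store root leaks the secret
  all_files <- list.files(st$root, recursive = TRUE, full.names = TRUE)
  for (f in all_files)
    expect_false(any(grepl("hunter2", readLines(f, warn = FALSE),
                           fixed = TRUE)), label = f)
})

test_that("template drift after a save is detected", {
  st <- store_open(tempfile("store"))
  t <- parse_template(fixture_path("minimal.xml"))
  store_register(st, t)
  b <- collect_bindings(t$window, list(input = "a.txt"))
  save_filled(st, t, b, "before drift")
  # re-register a modified template under the same id
  t$title <- "changed"
  store_register(st, t)
  expect_error(load_filled(st, "before drift"), "hash mismatch")
})
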