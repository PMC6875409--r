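test_that("bindings render booleans, flag paths, and respect defaults", {
  t <- stream_template()
  b <- collect_bindings(t$window, list(input = "inputFile", os = TRUE))
  expect_identical(b$values$os, "TRUE")
  expect_identical(b$values$input, "inputFile")
  expect_true("input" %in% b$path_typed)
  expect_true("outfile" %in% b$path_typed)
  # default fills the save dialog; unchecked group renders FALSE
  b2 <- collect_bindings(t$window, list(input = "x"))
  expect_identical(b2$values$os, "FALSE")
  expect_identical(b2$values$outfile, "output.txt")
  # missing value with no default names the element
  m <- parse_template(fixture_path("minimal.xml"))
  expect_error(collect_bindings(m$window, list()), "input")
  # non-boolean text for a checkbox is rejected
  cb <- parse_template(
    "<template id=\"t\"><window><checkbox id=\"v\"/><action/></window><execution><execute program=\"x\"><param>${v}</param></execute></execution></template>")
  expect_error(collect_bindings(cb$window, list(v = "maybe")), "TRUE/FALSE")
})

test_that("reference substitution follows the ${id} grammar", {
  ctx <- list(input = "inputFile")
  expect_identical(substitute_refs("no refs", ctx), "no refs")
  expect_identical(substitute_refs("cat ${input}", ctx), "cat inputFile")
  expect_identical(substitute_refs("$${input}", ctx), "${input}")
  expect_identical(substitute_refs("a$$b", ctx), "a$b")
  expect_error(substitute_refs("cat ${input", ctx), "unterminated")
  expect_error(substitute_refs("${nope}", ctx), "unresolved")
  expect_error(substitute_refs("${9bad}", ctx), "invalid reference")
})

test_that("network construction shares referenced nodes as single places", {
  model <- list(
    structure(list(kind = "const", id = "c", value = "-a "),
              class = "forge_exec_node"),
    structure(list(kind = "add", id = "a1", sep = "",
                   parts = list(list(type = "text", text = "${c}x"))),
              class = "forge_exec_node"),
    structure(list(kind = "add", id = "a2", sep = "",
                   parts = list(list(type = "text", text = "${c}y"))),
              class = "forge_exec_node"),
    structure(list(kind = "execute", id = "run", program = "p",
                   params = list(list(quote = NULL,
                                      fragment = list(list(type = "text",
                                                           text = "${a1}${a2}"))))),
              class = "forge_exec_node"))
  net <- build_network(model)
  expect_length(net$nodes, 4)
  # out-degree of the shared const is 2 (referenced by both adds)
  indeg <- sum(vapply(net$edges, function(e) "c" %in% e, logical(1)))
  expect_equal(indeg, 2)
  expect_equal(net$sinks, "run")

  # the shared node's transition fires exactly once under token semantics
  ctx <- eval_context(net, make_bindings(list()))
  evaluate_node("run", ctx)
  expect_equal(ctx$fired[["c"]], 1L)
  expect_identical(ctx$memo[["run"]], "-a x-a y")

  # appendix-style fixture: sink is the execute node over program sh
  net2 <- build_network(stream_template())
  expect_equal(net2$nodes[[net2$sinks]]$program, "sh")
})

test_that("node semantics: const, add, env, if", {
  const <- structure(list(kind = "const", id = "k", value = "-a "),
                     class = "forge_exec_node")
  net <- build_network(list(const, structure(
    list(kind = "execute", id = "run", program = "p",
         params = list(list(quote = NULL,
                            fragment = list(list(type = "text",
                                                 text = "${k}"))))),
    class = "forge_exec_node")))
  ctx <- eval_context(net, make_bindings(list()))
  expect_identical(evaluate_node("k", ctx), "-a ")

  model <- list(
    structure(list(kind = "add", id = "j", sep = "",
                   parts = list(list(type = "text", text = "netcat "),
                                list(type = "text", text = "192.168.1.100"),
                                list(type = "text", text = " 55025"))),
              class = "forge_exec_node"),
    structure(list(kind = "env", id = "e", key = "os"),
              class = "forge_exec_node"),
    structure(list(kind = "if", id = "i", probe = "${os}", equals = "TRUE",
                   then = list(list(type = "text", text = "yes")),
                   else_ = NULL),
              class = "forge_exec_node"),
    structure(list(kind = "execute", id = "run", program = "p",
                   params = list(list(quote = NULL,
                                      fragment = list(list(type = "text",
                                                           text = "${j}${e}${i}"))))),
              class = "forge_exec_node"))
  net <- build_network(model)
  ctx <- eval_context(net, make_bindings(list(os = "FALSE")),
                      env = list(os = "Windows"))
  expect_identical(evaluate_node("j", ctx), "netcat 192.168.1.100 55025")
  expect_identical(evaluate_node("e", ctx), "Windows")
  # absent else branch evaluates to empty text for any probe value
  expect_identical(evaluate_node("i", ctx), "")
  ctx2 <- eval_context(net, make_bindings(list(os = "TRUE")),
                       env = list(os = "Windows"))
  expect_identical(evaluate_node("i", ctx2), "yes")
  # unknown injected key errors
  ctx3 <- eval_context(net, make_bindings(list(os = "TRUE")),
                       env = list(other = "x"))
  expect_error(evaluate_node("e", ctx3), "unknown key 'os'")
  # add separator
  sep_add <- structure(list(kind = "add", id = "s", sep = ",",
                            parts = list(list(type = "text", text = "a"),
                                         list(type = "text", text = "b"))),
                       class = "forge_exec_node")
  net4 <- build_network(list(sep_add, model[[4]]))
  ctx4 <- eval_context(net4, make_bindings(list(os = "x")))
  expect_identical(evaluate_node("s", ctx4), "a,b")
})

test_that("worked-example assembly is string-exact for both branches", {
  t <- stream_template()
  inv <- assemble_invocation(
    t, collect_bindings(t$window, list(input = "inputFile", os = TRUE)))
  expect_length(inv, 1)
  expect_identical(inv[[1]]$program, "sh")
  expect_identical(inv[[1]]$argument_text,
                   "-c \"cat inputFile | netcat 192.168.1.100 55025\"")
  inv2 <- assemble_invocation(
    t, collect_bindings(t$window, list(input = "inputFile", os = FALSE,
                                       outfile = "/tmp/out.txt")))
  expect_identical(inv2[[1]]$argument_text,
                   "-c \"cat inputFile | tee -a /tmp/out.txt\"")
})

test_that("assembly is pure and deterministic", {
  t <- stream_template()
  b <- collect_bindings(t$window, list(input = "f", os = TRUE))
  wd <- getwd()
  snapshot <- list.files(tempdir(), recursive = TRUE)
  r1 <- assemble_invocation(t, b)
  expect_identical(getwd(), wd)
  expect_identical(list.files(tempdir(), recursive = TRUE), snapshot)
  r2 <- assemble_invocation(t, b)
  expect_identical(r1[[1]]$argument_text, r2[[1]]$argument_text)
  expect_identical(r1[[1]]$program, r2[[1]]$program)
})

test_that("memoized evaluation equals the naive recursive oracle", {
  set.seed(4711)
  for (rep in seq_len(120)) {
    gen <- random_exec_model()
    net <- build_network(gen$model)
    ctx <- eval_context(net, make_bindings(gen$element_vals),
                        env = gen$env)
    expected <- naive_eval(gen$model, gen$element_vals, gen$env)
    for (id in names(expected)) {
      expect_identical(evaluate_node(id, ctx), expected[[id]],
                       label = sprintf("rep %d node %s", rep, id))
    }
  }
})

test_that("cycles are rejected at network construction", {
  model <- list(
    structure(list(kind = "add", id = "A",
                   sep = "", parts = list(list(type = "text", text = "${B}"))),
              class = "forge_exec_node"),
    structure(list(kind = "add", id = "B",
                   sep = "", parts = list(list(type = "text", text = "${A}"))),
              class = "forge_exec_node"))
  expect_error(build_network(model), "cycle")
})
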