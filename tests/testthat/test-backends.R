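test_that("drive-letter paths translate per the wslpath convention", {
  expect_identical(translate_path_win_to_posix("C:\\Users\\luisa\\reads.fq"),
                   "/mnt/c/Users/luisa/reads.fq")
  expect_identical(translate_path_win_to_posix("D:\\"), "/mnt/d/")
  expect_identical(translate_path_win_to_posix("/already/posix/path"),
                   "/already/posix/path")
  expect_identical(translate_path_win_to_posix("not a path"), "not a path")
  expect_identical(translate_path_win_to_posix("E:\\dir with space\\f.txt"),
                   "/mnt/e/dir with space/f.txt")
  expect_identical(translate_path_posix_to_win("/mnt/c/Users/luisa/reads.fq"),
                   "C:\\Users\\luisa\\reads.fq")
})

test_that("win -> posix -> win is identity on generated drive paths", {
  set.seed(55025)
  for (i in seq_len(1000)) {
    p <- random_win_path()
    expect_identical(translate_path_posix_to_win(
      translate_path_win_to_posix(p)), p, label = p)
  }
})

test_that("backend construction is pure and wraps the same command", {
  t <- stream_template()
  inv <- assemble_invocation(
    t, collect_bindings(t$window, list(input = "inputFile", os = TRUE)))[[1]]
  wd <- getwd()
  snapshot <- list.files(tempdir(), recursive = TRUE)

  native <- build_backend_command(inv, backend_native())
  expect_identical(native$argv,
                   c("sh", "-c",
                     "sh -c \"cat inputFile | netcat 192.168.1.100 55025\""))

  wsl <- build_backend_command(inv, backend_wsl())
  expect_identical(wsl$argv[1], "wsl.exe")
  # backend transparency: identical embedded command up to wrapper tokens
  expect_identical(wsl$argv[length(wsl$argv)],
                   native$argv[length(native$argv)])

  docker <- build_backend_command(
    inv, backend_docker(image = "circlator", mounts = c("/data" = "/data")))
  expect_identical(docker$argv[1:5],
                   c("docker", "run", "-v", "/data:/data", "circlator"))
  expect_identical(docker$argv[length(docker$argv)],
                   native$argv[length(native$argv)])

  remote <- build_backend_command(inv, backend_remote(host = "node7",
                                                      port = 2222))
  expect_identical(remote$argv[1:4], c("ssh", "-p", "2222", "node7"))

  stream <- build_backend_command(
    inv, backend_remote(host = "node7", transport = "stream",
                        stream_host = "192.168.1.100",
                        stream_port = 55025))
  expect_match(stream$argv[length(stream$argv)],
               "\\| nc 192.168.1.100 55025$")

  http <- build_backend_command(inv, backend_http("http://svc/run"))
  expect_identical(http$request$method, "POST")
  expect_identical(http$request$fields$input, "inputFile")

  # construction spawned nothing and touched nothing
  expect_identical(getwd(), wd)
  expect_identical(list.files(tempdir(), recursive = TRUE), snapshot)
})

test_that("wsl runnables pre-translate path-typed binding values only", {
  t <- stream_template()
  b <- collect_bindings(t$window, list(input = "C:\\d\\in.fq", os = FALSE,
                                       outfile = "C:\\o\\out.txt"))
  inv <- assemble_invocation(t, b)[[1]]
  wsl <- build_backend_command(inv, backend_wsl())
  cmd <- wsl$argv[length(wsl$argv)]
  expect_match(cmd, "/mnt/c/d/in.fq", fixed = TRUE)
  expect_match(cmd, "/mnt/c/o/out.txt", fixed = TRUE)
  # a non-path binding that merely looks like a path is left alone
  t2 <- parse_template(
    "<template id=\"t\"><window><input id=\"u\"/><action/></window><execution><execute program=\"curl\"><param>${u}</param></execute></execution></template>")
  inv2 <- assemble_invocation(t2, collect_bindings(t2$window,
                                                   list(u = "C:\\fake")))[[1]]
  wsl2 <- build_backend_command(inv2, backend_wsl())
  expect_match(wsl2$argv[length(wsl2$argv)], "C:\\fake", fixed = TRUE)
})

test_that("invalid backend configuration errors at construction", {
  expect_error(backend_docker(image = ""), "image")
  expect_error(backend_http(url = ""), "URL")
})

test_that("execution captures output, status and channel order", {
  res <- execute(c("sh", "-c", "echo hi"))
  expect_identical(res$exit_status, 0L)
  expect_identical(res$records$channel, "out")
  expect_identical(res$records$line, "hi")

  res3 <- execute(c("sh", "-c", "exit 3"))
  expect_identical(res3$exit_status, 3L)

  two <- execute(c("sh", "-c", "echo first; echo second; echo oops >&2"))
  out <- two$records[two$records$channel == "out", "line"]
  expect_identical(out, c("first", "second"))
  expect_identical(two$records[two$records$channel == "err", "line"], "oops")

  missing <- execute(c("definitely-not-a-program-xyz"))
  expect_identical(missing$exit_status, 127L)

  slow <- execute(c("sh", "-c", "sleep 5"), timeout = 1)
  expect_identical(slow$exit_status, 124L)
  expect_true(slow$timed_out)
})

test_that("assembled invocations execute end to end through a backend", {
  t <- parse_template(
    "<template id=\"t\"><window><input id=\"msg\" default=\"ping\"/><action/></window><execution><execute program=\"echo\"><param>${msg}</param></execute></execution></template>")
  inv <- assemble_invocation(t, collect_bindings(t$window, list()))[[1]]
  res <- execute(build_backend_command(inv, backend_native()))
  expect_identical(res$exit_status, 0L)
  expect_identical(res$records$line, "ping")
})
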