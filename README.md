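# cmdforge

Declarative templates for assembling — and optionally running —
command-line invocations of bioinformatics tools.

Most bioinformatics methods ship as command-line programs, which puts them
out of reach of many of the scientists who need them, and makes runs hard
to reproduce ("which flags did I use in March?"). `cmdforge` is a headless
R implementation of the template-framework idea behind GUI front ends for
such tools: a small XML dialect describes, in one document,

* a **window model** — the form a user fills in (labels, text inputs,
  check boxes, file dialogs, combo boxes, checkable group boxes, one
  action button, a stream box for program output); and
* an **execution model** — a dataflow graph of `const`, `add`, `env`,
  `if`, `script` and `execute` nodes that turns the filled-in values into
  the argument string of one or more programs.

Any text in the execution model may reference a form value or another node
as `${id}`. Evaluation follows petri-net token semantics: every node is a
place, its function the transition, and a transition fires once all of its
input places carry values — realised here as demand-driven, memoized
evaluation over an acyclic graph, so each node produces exactly one token
per assembly and identical inputs always yield identical commands.

Around that core the package provides:

* a sandboxed **embedded scripting dialect** (a Lua subset with Lua-style
  pattern matching) for string manipulation inside templates, e.g.
  stripping `.1.ht2` from a HISAT2 index file name;
* **execution backends**: native shell, WSL (with `X:\...` →
  `/mnt/x/...` drive-letter path translation), ssh, HTTP POST and Docker,
  plus line-streamed output capture;
* **template generators** from CWL `CommandLineTool` documents and from
  neutral CLI-parser specifications, with the fallback rule that any
  unrecognised input type becomes a plain text input;
* an **install-module runner** with a stable positional argument contract
  (`install_dir, add_to_path, sudo_password, extras...`) and recovery of
  the template a module ships; and
* a local **template store** with saved filled templates, so a run's exact
  parameters can be reloaded and reassembled later.

## Worked example

The shipped fixture `stream-example.xml` is a template that either streams
a chosen file to a network listener or appends it to a local file,
depending on a checkable group box:

```r
library(cmdforge)
t <- parse_template(system.file("extdata", "stream-example.xml",
                                package = "cmdforge"))
b <- collect_bindings(t$window, list(input = "inputFile", os = TRUE))
assemble_invocation(t, b)[[1]]
#> <invocation> sh -c "cat inputFile | netcat 192.168.1.100 55025"
#>   backend: native
```

The check box bound to `os` is rendered as the string `"TRUE"`, the `if`
node therefore picks the `netcat` branch, and the `execute` node's params
assemble to the argument text shown. Unchecking the box and supplying an
output path flips the pipeline to `tee`:

```r
b2 <- collect_bindings(t$window, list(input = "inputFile", os = FALSE,
                                      outfile = "/tmp/out.txt"))
assemble_invocation(t, b2)[[1]]$argument_text
#> [1] "-c \"cat inputFile | tee -a /tmp/out.txt\""
```

Assembly is pure — nothing runs until you ask:

```r
inv <- assemble_invocation(t, b)[[1]]
build_backend_command(inv, backend_native())$argv
#> [1] "sh" "-c" "sh -c \"cat inputFile | netcat 192.168.1.100 55025\""
```

Generating a template from a CWL description and running it end to end:

```r
spec <- from_cwl(system.file("extdata", "wc-tool.cwl", package = "cmdforge"))
t2 <- from_cli_spec(spec)
inv <- assemble_invocation(t2, collect_bindings(t2$window,
                                                list(infile = "f.txt")))[[1]]
paste(inv$program, inv$argument_text)
#> [1] "wc -c f.txt"
```

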