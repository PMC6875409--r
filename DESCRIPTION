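Package: cmdforge
Title: Declarative Templates for Assembling and Running Command-Line Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless framework that turns declarative XML templates into
    runnable command-line invocations. A template has two parts: a window
    model describing a form (file dialogs, check boxes, combo boxes,
    checkable groups) and an execution model, a dataflow graph of constant,
    concatenation, environment, conditional and script nodes that is
    evaluated with token (petri-net) semantics over the user's input values
    to assemble the argument string of one or more programs. Includes an
    embedded sandboxed scripting dialect with Lua-style pattern matching for
    string manipulation inside templates, execution backends (native shell,
    Windows Subsystem for Linux with drive-letter path translation, ssh,
    HTTP POST, Docker), template generators from Common Workflow Language
    CommandLineTool documents and neutral command-line parser
    specifications, an install-module runner with a stable positional
    argument contract, and a local template store with saved, reproducible
    filled templates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
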