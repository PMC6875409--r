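---
title: "How cmdforge templates work: the form model, the dataflow engine, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How cmdforge templates work}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmdforge)
```

## The problem and the model

Command-line bioinformatics tools are parameterised by flags and paths; a
form-based front end needs two things: a description of the inputs to
collect, and a recipe for turning the collected values into an argument
string. `cmdforge` keeps both in one XML document, deliberately separated:

* The **window model** is a tree of widgets. Only some widget kinds carry a
  value — text inputs, check boxes, file dialogs, combo boxes, and
  *checkable* group boxes (whose value is whether they are checked).
  Labels, the action button and the stream box are presentation only.
* The **execution model** is a list of nodes forming a directed acyclic
  graph. `const` holds a literal, `add` concatenates its parts (optionally
  with a separator), `env` reads an environment variable, `if` compares a
  probed value against a constant and yields one of two branches, `script`
  computes a value in an embedded scripting dialect, and `execute` names a
  program and the ordered params of its argument string. Text anywhere in
  these nodes may reference a widget value or another node as `${id}`;
  `$$` escapes a literal dollar.

Booleans are rendered as the strings `"TRUE"`/`"FALSE"` before the engine
sees them, so an `if` with `equals="TRUE"` probes a check box directly.
This keeps the comparison machine-rendered and exact; string comparison in
`if` nodes is case-sensitive by design.

## Token semantics

Evaluation is specified as a petri net: each node is a place, its function
a transition, and a transition needs tokens on **all** of its input places
before it can produce its own token. Because the graph is acyclic and every
node is pure, the implementation realises this as demand-driven memoized
recursion: a node's transition fires at most once per assembly, no matter
how many parents reference it, and each place holds exactly one token. The
test suite checks this against a deliberately naive oracle — plain
recursive re-evaluation with no memoization and none of the engine's
machinery — over randomly generated acyclic networks (up to 30 nodes); both
must agree exactly, and an instrumented counter verifies a shared node
fires once.

Decisions taken where the model was open:

* An `if` without an `else` branch evaluates to empty text, keeping
  assembly total for every probe value.
* Params of an `execute` node that evaluate to empty text are omitted from
  the joined argument string. This keeps conditionally-emitted flags (a
  boolean's gated flag, an optional option left blank) from leaving stray
  double spaces. Params are joined with single spaces.
* The engine injects no shell quoting; templates control their own quoting
  (the worked streaming example embeds its quotes in the param text). A
  param may opt in to `quote="shell"`, which wraps its value in double
  quotes and escapes embedded ones.
* Multiple `execute` nodes assemble in document order.
* Ids share one namespace across the window and execution models, so a
  `${ref}` is never ambiguous; duplicates are validation errors.
* The `env` node reads an *injected* environment when one is supplied
  (tests and saved-run reproduction do this for hermeticity) and the live
  process environment otherwise.

## The embedded scripting dialect

Templates sometimes need genuine string manipulation — the canonical case
is stripping the numbered extension from a HISAT2 index file so the tool
accepts the index prefix. Script nodes hold a function named `evaluate` in
a small Lua-subset dialect, called with the node's `argv` references in
order; the last return value of the call stack, rendered as text, is the
node's token.

The interpreter is written in R and supports what template scripts
realistically use: functions, `local`, `if`/`elseif`/`else`, `while`,
multiple return values with Lua's expression-list adjustment, `and`/`or`/
`not`, comparison, concatenation (`..`), arithmetic, string-method sugar
(`s:find(p)`), and a string library (`match`, `find`, `sub`, `gsub`,
`len`, `upper`, `lower`, `rep`, `reverse`) backed by a Lua-style pattern
matcher (`.`, `%d`-style classes with uppercase complements, `[sets]` with
ranges, quantifiers `*` `+` `-` `?`, anchors `^` `$`). Lua's indexing
conventions are preserved — `string.sub(s, 0, j)` treats 0 as 1, negative
indices count from the end — because template scripts written against the
dialect rely on them.

Sandboxing is by construction: the interpreter's global environment
contains only these pure primitives, so `io`, `os`, `require` and friends
are `nil` and any attempt to touch files, processes or the network fails
with a script error. Two resource caps bound execution: a step budget
(default 1e6 interpreter steps) and a wall-clock limit (default 5 s).
Unbounded scripts would otherwise break the guarantee that assembly always
terminates. Both caps are arguments of `evaluate_script()`.

The pattern matcher is verified against an independent oracle: a
translation of the pattern subset into PCRE evaluated by R's own regex
engine, on 1,000 seeded random file names per run. Dialect details the
oracle cannot express (malformed-pattern errors, `$` inside a pattern) are
covered by directed cases.

## Backends and path translation

Assembly and backend construction are both pure; only `execute()` touches
the system. The native backend wraps the assembled command as
`[shell, "-c", program + " " + arguments]`; WSL wraps the same text for
the WSL entry point and pre-translates every *path-typed* binding value
(file-dialog values) with the `X:\a\b` → `/mnt/x/a/b` drive-letter rule.
Translation deliberately applies only to path-typed values, not to
arbitrary argument text, so URLs or flags that merely look like paths are
never corrupted. The translation is implemented textually on the assembled
string: if a path value also occurs as an unrelated substring of the
command, that occurrence is translated too — a documented limitation that
does not arise in practice because path values come from file dialogs.

The ssh backend wraps the command for a remote host; the remote-stream
variant pipes the remote stdout to a TCP listener (line-oriented text, a
convention of this package — no wire protocol is inherited). The HTTP
backend encodes bindings as an urlencoded POST form, field names equal to
element ids, and treats the response body as output records; its
construction is fully tested, while the live exchange runs only against a
real endpoint. Docker prepends `docker run` with one `-v host:container`
per mount. Output capture records lines per channel in arrival order;
order *across* the two channels is not defined. Exit statuses follow shell
conventions (124 timeout, 127 not found).

## Generators

`from_cwl()` reads the CWL `CommandLineTool` subset (v1.0–v1.2):
`baseCommand`, inputs in map or array form, the primitive types, enums,
optional types, `inputBinding.prefix`/`.position`, `doc`/`label` as help
text. Outputs, requirements, hints and expressions are ignored with a
warning — only the input-to-argument mapping is consumed. `from_cli_spec()`
then emits one widget per input with a fixed mapping (boolean → check box,
file/directory → file dialog, enum → combo box, numbers and strings →
text input) and the important fallback: anything unrecognised becomes a
text input, so a widget always exists and coverage is total. Boolean flags
follow the store-true convention — the flag is emitted when the box is
checked and nothing otherwise — and optional flagged inputs are gated on
the empty string, so leaving them blank leaves no trace in the command.
Widget labels use the input's help text (truncated at 60 characters) when
present, else its name. One level of subcommands is supported: a combo box
selects the subcommand and per-subcommand argument groups are gated by
`if` nodes on its value.

## Install modules and the store

Install modules are plain shell scripts with a fixed ABI, so they are
writable without reference to this package: `$1` install directory, `$2`
`"TRUE"`/`"FALSE"` for add-to-path, `$3` the sudo password or an empty
placeholder, then any declared extra inputs, strictly last and in declared
order. Because a positional secret is visible to the local process list,
the runner also exports it as `FORGE_SUDO_PASSWORD` for modules that
prefer the environment channel. Display and serialization of install
invocations mask the password slot, and secret-flagged values are never
written by the store.

A module may embed the template for the tool it installs between
`### TEMPLATE-BEGIN` and `### TEMPLATE-END` lines (leading `#` markers are
stripped); after a successful install the runner extracts, parses and
registers it. A malformed block yields a diagnostic but leaves the module
usable for installation.

The store is a plain directory — `manifest.json`, `templates/`, `filled/`
— chosen for diff-ability and zero-dependency portability. Saved filled
templates record the binding values (minus secrets) plus a content hash of
the template, so reloading detects template drift instead of silently
reassembling a different command.

## What the synthetic test inputs emulate — and what they do not

All verification inputs are generated in code: random acyclic execution
networks (const/add/if/env over ≤ 30 nodes, references always pointing
backwards), random file names over `[a-z0-9.]` with random patterns from
the dialect subset, random drive-letter paths (depth ≤ 6, names that may
contain interior spaces), and random CLI specifications over all eight
value types. These exercise the engine's semantics — sharing, memoization,
branch totality, reference resolution — and the generators' coverage rule.
They do not emulate real GUI sessions (no widget toolkit is rendered), a
real WSL host, a Docker daemon, a remote cluster or a live web service;
backend tests therefore verify the *constructed* runnables exactly and
execute only local shell commands. Passing tests show the assembly
pipeline is correct and deterministic, not that any particular external
tool installs or runs correctly.

Per-run problem sizes in the test suite and acceptance script — 1,000
file-name/pattern pairs, 100 random networks, 1,000 translated paths, 50
random CLI specs, three saved-run repetitions per fixture — were chosen so
that each property sees a broad input sample while a full run stays
comfortably interactive.

## Known limitations

* The XML dialect matches the semantics of the original template idea but
  defines its own tag and attribute vocabulary; no byte-level
  compatibility with any external template collection is promised.
* Scripts run in one dialect (the Lua subset); registering additional
  dialects is supported via `register_dialect()`.
* The WSL wrapper token sequence (`wsl.exe sh -c ...`) is fixed by this
  package and documented rather than probed from a live system.
* HTTP execution performs a real network exchange and is not exercised by
  the offline test suite.
* Group boxes always bind their children; an unchecked checkable group
  leaves its children's values available to the execution model (the
  streaming example's `else` branch relies on exactly this).
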