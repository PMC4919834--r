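---
title: "Provenance logging: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Provenance logging: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runinfo)
```

## The problem

Reproducing a computational analysis needs more than the code and the raw
data: the result of a pipeline run also depends on the versions of every
loaded library, the interpreter build, the C runtime underneath it, the
operating system, the machine, the user identity, and the exact invocation.
Pipelines in genomics routinely chain a dozen tools, each with its own
release cadence, so two well-intentioned re-runs of "the same" analysis can
silently disagree because one loaded package moved a minor version.

`runinfo` addresses this with a single activation line in the host program:

```r
runinfo::activate()
```

Nothing else changes in the program. When it terminates — normally, or
killed by a catchable signal — a machine-parseable log of the complete
execution environment is written. The log can be published alongside
results, archived with the run's outputs, and later compared against
another run's log to find environment differences that might affect (or
explain) divergent results.

## What is captured

Each log is a sequence of `TAG: payload` records in a fixed canonical
order:

| Tags | Content |
|---|---|
| `MODULE`\* | one record per loaded package: name, version, installed location, checksum |
| `INC`\* | the library search path, in order, duplicates preserved |
| `UNAME` | OS name, host, release, version, machine |
| `PROC0..n` | per-processor model/cores/clock (plus total memory on `PROC0`) |
| `INTERP`, `INTERPVer`, `INTERPSum` | interpreter binary path, version, SHA-256 |
| `LIBC`, `LIBCSum` | C runtime library version and SHA-256 |
| `User`, `Group`\* | effective identities; real ones only when different |
| `ProgDir`, `Program`, `Version`, `ProgSUM` | the main program file and its checksum |
| `Args` | argument count, then each argument individually quoted |
| `Start`, `End`, `Elapsed`, `EndStat` | the execution window and exit status |
| program-specified | records appended by `register_extra_logger()` callbacks |

Two `META` header records (`format-version`, `hash-algorithm`) make every
log self-describing, so a parser can verify digests without out-of-band
knowledge.

Snapshots are taken at emission time, not activation time, so packages
loaded late in the run are included. The command-line arguments are the
exception: they are copied at activation, before the program can mutate
them.

## Capture can never break the host

A provenance logger that crashes the pipeline it documents is worse than
none. Every capture operation is therefore infallible by construction:
unobtainable values become the sentinel `"UNKNOWN"` (never an empty
string, so parsed documents have no missing-vs-empty ambiguity), a module
whose file has vanished keeps its record with an `"UNKNOWN"` checksum, and
the emission path is wrapped so a failure produces one diagnostic message
rather than an exception in the host's shutdown sequence.

## Termination hooks and signal semantics

Normal termination uses an exit finalizer registered at first activation.
Signal-triggered termination needs C support, since R cannot trap POSIX
signals natively: handlers are installed with `sigaction` for `SIGTERM`,
`SIGINT`, `SIGQUIT` and `SIGHUP` (never untrappable signals such as
`SIGKILL`). A handler emits the log, invokes any plain handler the host
had installed before activation, then restores the default disposition
and re-raises — so the parent process observes a genuine signal death
with the conventional status, not a disguised exit code.

Three design points deserve attention:

* **Exactly-once emission.** Multiple signals, or a signal arriving while
  the exit hook is already writing, must not produce two logs. The guard
  is a C-level `sig_atomic_t` test-and-set taken before any I/O; an R
  flag alone would not be interrupt-safe. The log is additionally written
  to a hidden temporary name and renamed into place atomically, so a run
  leaves either one complete log or none — never a truncated one under a
  `.runinfo` name.
* **`SIGINT` is shared with R.** During interruptible waits such as
  `Sys.sleep()`, R temporarily owns `SIGINT` for its user-interrupt
  machinery; an interrupt delivered there follows R's semantics (the
  program errors out and the log is still written by the exit hook, with
  `EndStat` 0). A `SIGINT` delivered while the program is computing
  reaches the handler and is logged as `SIGINT`. `SIGTERM`/`SIGHUP`/
  `SIGQUIT` are unaffected.
* **Hosts that reset handlers.** A program that later resets a handler to
  the default disposition forfeits signal-time logging for that signal.
  This is accepted: a program dying of unhandled signals is not yet
  producing publishable results, though the log is then also unavailable
  as a diagnostic aid.

`EndStat` for a normal exit is recorded as `0`: R exit finalizers cannot
observe a non-zero status passed to `quit()`, which is a genuine
limitation of the runtime (an END-block in other languages can inspect
the pending status).

## Options and precedence

Options resolve in three layers: built-in defaults, then each
`activate()` call's options in order (so a shared configuration module
can set a baseline that individual programs override), then the
`RUNINFO_*` environment variables saved at first activation. Environment
variables are re-applied after every merge, which makes the precedence
`defaults < activation layers < environment` a stable law rather than an
accident of call order; a single run can thus be suppressed
(`RUNINFO_SUPPRESS=1`), redirected (`RUNINFO_DIR=...`), or made to
checksum every module (`RUNINFO_MODULE_CHECKSUMS=1`) without touching
the program.

Defaults, with rationale:

* `enabled = TRUE`, `log_dir = "."`, `log_name = "AUTO"` — the automatic
  name `<program>.<YYYYMMDD-HHMMSS>.runinfo` embeds the program name and
  a local-time stamp so separate runs are distinguishable. If two runs
  share a wall-clock second, emission appends a `-<k>` suffix rather than
  overwriting.
* `announce = TRUE` — one line on the diagnostic stream,
  `runinfo: log written to <path>`, so an interactive user learns where
  the log went.
* `module_checksums = FALSE` — hashing every loaded package on every run
  costs time most runs do not want to spend; the per-module checksum
  field then holds `"UNKNOWN"`. Enable it (option or environment
  variable) when preparing a run for publication.
* `forward_target = NULL` — when set to a function or a file path, the
  rendered log lines are also delivered to that host logging facility.
  The native file is still written: output embedded in another
  framework's log is typically decorated and no longer parseable, so the
  canonical artifact must exist independently.

The hash is fixed as SHA-256 (64 hex characters): collision-resistant,
universally available, and named in the `META` header so future
algorithm changes remain parseable.

## The log format

The format is deliberately minimal so that it is trivially parseable in
any language: one record per line as `TAG: payload`, UTF-8, LF endings.
Payloads longer than the render width (default 80) wrap at whitespace
onto continuation lines beginning `"+ "`; the wrapper only breaks at
isolated single spaces, so rejoining continuations with a single space
reproduces the payload byte-for-byte — the round-trip
`parse(render(doc))` is an identity, property-tested across generated
documents at widths 40, 80 and unlimited. A single token longer than the
width (a checksum, say) is emitted unbroken rather than split. Fields
within `MODULE` and `Args` payloads that contain spaces are quoted with
backslash escaping; `parse_module_payload()` inverts that quoting.

Parse errors (a continuation with no predecessor, a line with no
separator) are reported with their line numbers. Unknown tags are
preserved, not rejected: program-specified tags are open-ended by
design.

## Comparing two runs

`diff_documents()` classifies differences between two parsed logs.
Modules are matched by name, not list position — load order is
environment noise, and the purpose is detecting substantive differences:
a version mismatch is `module-version`, a content change
`module-checksum`, and unmatched names `module-added`/`module-removed`.
Remaining tags are compared literally, repeated tags as ordered lists,
and processors per index (a count change additionally yields one summary
entry). `Start`/`End`/`Elapsed` are ignored by default because
timestamps always differ between runs; `EndStat` and `Args` are compared
by default because differing arguments or exit status plausibly explain
differing results. A matched module whose installed path alone changed
is reported under the catch-all `extra` category: a relocation is worth
surfacing but is neither a version nor a content change. No semantic
version reasoning is attempted (`1.0` vs `1.0.0` is a difference);
deciding which differences are benign is left to the analyst.

## The fixture generator

Format and diff behavior are tested against generated documents, not
stored files. `generate_fixture()` produces a pseudo-random but
realistic document — module lists with plausible names, versions, paths
and digest-width checksums; system, interpreter, user, program and
timing records — deterministically from a seed (byte-identical renders
for identical specs, with the caller's RNG state saved and restored).
When perturbations are requested, a second document is derived by
applying exactly those perturbations, each mapping to exactly one diff
entry of the same category; unnamed module perturbations draw distinct
target modules so the injected set and the report correspond one-to-one.
The derived document always receives a fresh execution window, which is
what two honest runs look like, so the default ignore set is exercised
by every pair.

What the generator does not emulate: real logs have correlated content
(module versions consistent with one release epoch, paths under one
library root), hostnames and hardware that recur across runs, and
occasionally hand-edited files. Passing the generated-document
properties therefore demonstrates format and diff correctness, not
robustness to arbitrarily mangled third-party logs.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen to exercise each property
well past the point where defects of the relevant kind appear: 1000
generated documents at three wrap widths for the round-trip identity,
500 perturbed pairs for diff fidelity, 100 random files against an
independent `sha256sum` oracle for checksums, 50 subprocess trials with
concurrent `SIGTERM` delivery for the exactly-once guarantee, and one
real instrumented subprocess per signal for signal-time logging.

## Known limitations

* Signal-time logging is POSIX-only; on Windows only normal-exit logging
  is available.
* `EndStat` cannot reflect a non-zero `quit()` status (see above).
* C-library identification is inherently approximate: the version comes
  from the glibc configuration string and the checksum from the mapped
  `libc` shared object; static linking or non-glibc platforms yield
  `"UNKNOWN"`. No attempt is made to introspect linked libraries beyond
  the C runtime.
* A package's recorded checksum target is its `DESCRIPTION` file — a
  package is a directory, and hashing one canonical member detects
  version/build changes cheaply; it does not detect a patched source
  file inside an installed tree (enable `module_checksums` and compare
  versions and paths as well).
* Emission from a signal handler executes R code at an asynchronous
  point; the handler terminates the process immediately afterwards, so
  inconsistent interpreter state cannot propagate, but an emission that
  fails mid-write under these conditions leaves no log (never a corrupt
  one, thanks to the atomic rename).
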