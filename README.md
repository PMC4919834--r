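# runinfo

Runtime provenance logs for reproducible R pipelines.

Reproducing a computational analysis requires knowing the environment it
ran in: the versions and locations of every loaded package, the
interpreter build and the C runtime under it, the operating system and
hardware, the user, the program file, and the exact command line. That
context is rarely recorded, and when two runs of "the same" pipeline
disagree, it is exactly what you need to explain why.

`runinfo` records all of it with one line in the host program:

```r
runinfo::activate()
```

When the program terminates — normally **or killed by a catchable signal
(`TERM`, `INT`, `HUP`, `QUIT`)** — a machine-parseable log of the complete
execution environment is written, exactly once, named
`<program>.<YYYYMMDD-HHMMSS>.runinfo` by default. The package also ships
the parser for the format, a classified diff of two runs' environments,
and a small command-line tool.

## The log

One record per line, `TAG: payload`, with long payloads wrapped onto
`"+ "` continuation lines; a `META` header names the format version and
hash algorithm so every log is self-describing:

```
META: format-version 1.0
META: hash-algorithm sha256
MODULE: askpass 1.2.1 /opt/conda/envs/bio/lib/R/library/askpass UNKNOWN
MODULE: base 4.3.3 /opt/conda/envs/bio/lib/R/library/base UNKNOWN
MODULE: compiler 4.3.3 /opt/conda/envs/bio/lib/R/library/compiler UNKNOWN
...
INC: /root/.R/library
INC: /opt/conda/envs/bio/lib/R/library
UNAME: Linux vm 6.18.44-fc-v42 #1 SMP PREEMPT_DYNAMIC @0 x86_64
...
```

followed by per-processor records, the interpreter and libc identity
with SHA-256 checksums, user and group identities (real IDs only when
they differ from the effective ones), the program file and its checksum,
the quoted argument vector, the execution window (`Start`, `End`,
`Elapsed`, `EndStat` — the exit status or the signal name, e.g.
`SIGTERM`), and any records appended by program-registered callbacks.

Options resolve as `defaults < activate() layers < RUNINFO_* environment
variables`, so a single run can be suppressed (`RUNINFO_SUPPRESS=1`),
redirected (`RUNINFO_DIR=...`), or made to checksum every loaded module
(`RUNINFO_MODULE_CHECKSUMS=1`) without touching the program. A
`forward_target` additionally delivers the rendered lines to a host
logging facility while still writing the native file.

## Worked example

Run the bundled instrumented demo program:

```sh
$ Rscript $(Rscript -e 'cat(system.file("exec","runinfo",package="runinfo"))') demo --dir logs
Hello, world!
runinfo: log written to logs/simple.R.20260928-111710.runinfo
```

Two lines: the program's own output, and the logger's announcement on
the diagnostic stream. The named file parses cleanly and contains every
mandatory record class (`runinfo validate <file>` checks this).

Generate a deterministic pair of synthetic logs differing by a module
version bump and an extra command-line argument, then diff them:

```sh
$ runinfo fixture --seed 42 --modules 5 --perturb module-version --perturb args --dir logs
logs/fixture-42-a.runinfo
logs/fixture-42-b.runinfo
$ runinfo diff logs/fixture-42-a.runinfo logs/fixture-42-b.runinfo
module-version: MODULE seppracor: 8.9.7 -> 6.2.9
args: Args: 2 "--input" "run20.dat" -> 3 "--input" "run20.dat" "--rerun"
$ echo $?
1
```

Each line is one classified difference: the module `seppracor` changed
version between the runs, and the second run was invoked with an extra
`--rerun` argument. Exit status 1 means "differences found" (0 = match,
2 = usage error, 3 = parse/IO failure), so the diff is script-friendly.
Timestamps (`Start`/`End`/`Elapsed`) are ignored by default — two runs
of an identical environment diff as `environments match`.

The same operations are available as R functions: `parse_document()`,
`validate_document()`, `diff_documents()`, `summarize_report()`,
`generate_fixture()`, and the capture layer (`snapshot_modules()`,
`snapshot_system()`, ...) used by `emit()`.

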