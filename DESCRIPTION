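Package: runinfo
Title: Runtime Provenance Logs for Reproducible Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Records the complete execution environment of an R program in a
    machine-parseable log file written at termination, including abnormal
    termination by catchable signal. One activation line captures the loaded
    package set (names, versions, locations, optional checksums), the library
    search path, operating system and processor details, the interpreter and C
    runtime library, user and group identities, the program file and its
    command-line arguments, and the execution window. Ships a parser for the
    log format, a classified diff of two executions' environments, and a small
    command-line tool (validate, show, diff, demo, fixture generation) so that
    divergent pipeline runs can be traced to environment differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    openssl,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    processx,
    testthat (>= 3.0.0),
    withr
SystemRequirements: POSIX signal handling (signal-triggered logging is
    unavailable on Windows; normal-exit logging works everywhere)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
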