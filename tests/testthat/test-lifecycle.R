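test_that("option resolution follows defaults < layers < environment", {
  d <- default_options()
  expect_identical(resolve_options(d, list(), list()), d)  # identity

  r <- resolve_options(d, list(list(log_dir = "/a"), list(log_dir = "/b")))
  expect_identical(r$log_dir, "/b")  # later layers win

  r2 <- resolve_options(d, list(list(enabled = TRUE)),
                        list(RUNINFO_SUPPRESS = "1"))
  expect_false(r2$enabled)  # environment overrides activation

  r3 <- resolve_options(d, list(), list(RUNINFO_DIR = "/elsewhere",
                                        RUNINFO_MODULE_CHECKSUMS = "true"))
  expect_identical(r3$log_dir, "/elsewhere")
  expect_true(r3$module_checksums)
})

test_that("environment application is last and idempotent (precedence law)", {
  d <- default_options()
  set.seed(99)
  dirs <- c("/p", "/q", "/r")
  for (i in 1:20) {
    layers <- lapply(seq_len(sample(0:3, 1)), function(j) {
      stats::setNames(list(sample(dirs, 1)), sample(c("log_dir", "log_name"), 1))
    })
    env <- if (i %% 2 == 0) list(RUNINFO_DIR = "/env", RUNINFO_SUPPRESS = "0")
           else list()
    one_pass <- resolve_options(d, layers, env)
    two_pass <- resolve_options(resolve_options(d, layers, list()), list(), env)
    expect_identical(one_pass, two_pass)
  }
})

test_that("malformed or unknown environment options warn and are ignored", {
  d <- default_options()
  expect_warning(r <- resolve_options(d, list(), list(RUNINFO_SUPPRESS = "maybe")),
                 "malformed")
  expect_true(r$enabled)
  expect_warning(resolve_options(d, list(), list(RUNINFO_BOGUS = "1")),
                 "unknown")
  expect_warning(resolve_options(d, list(list(bogus_option = 1))), "unknown")
})

test_that("activation merges layers, first call wins for setup state", {
  ri_local_state()
  s1 <- activate(enabled = FALSE, hooks = FALSE)
  expect_false(s1$options$enabled)
  t1 <- s1$start_time
  Sys.sleep(0.05)
  s2 <- activate(enabled = TRUE, hooks = FALSE)
  expect_true(s2$options$enabled)      # later call wins
  expect_identical(s2$start_time, t1)  # start time set on first call only
  expect_identical(s2$argv, s1$argv)
})

test_that("saved environment overrides are re-applied after every merge", {
  ri_local_state()
  withr::local_envvar(RUNINFO_SUPPRESS = "1")
  activate(hooks = FALSE)
  s <- activate(enabled = TRUE, hooks = FALSE)
  expect_false(s$options$enabled)  # env survives later activation layers
})

test_that("emission writes exactly one log and is then a no-op", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  activate(hooks = FALSE, log_dir = tmp, log_name = "run.runinfo",
           announce = FALSE)
  p1 <- emit()
  expect_identical(basename(p1), "run.runinfo")
  doc <- parse_document(readLines(p1))
  expect_length(validate_document(doc), 0)
  expect_null(emit())  # second call: no-op returning absent
  expect_identical(ri_logs_in(tmp), "run.runinfo")
})

test_that("emission is suppressed when logging is disabled", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  activate(hooks = FALSE, log_dir = tmp, enabled = FALSE)
  expect_null(emit())
  expect_length(ri_logs_in(tmp), 0)
})

test_that("extra loggers append after standard records, in order, fault-tolerantly", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  activate(hooks = FALSE, log_dir = tmp, log_name = "x.runinfo",
           announce = FALSE)
  register_extra_logger(function(append) append("SAMPLES", "42"))
  register_extra_logger(function(append) stop("boom"))
  register_extra_logger(function(append) append("COHORT", "trial-A"))
  path <- emit()
  doc <- parse_document(readLines(path))
  n <- nrow(doc$records)
  tail3 <- doc$records$tag[(n - 2):n]
  expect_identical(tail3, c("SAMPLES", "ExtraLoggerError", "COHORT"))
  expect_identical(doc$records$payload[doc$records$tag == "SAMPLES"], "42")
  expect_match(doc$records$payload[doc$records$tag == "ExtraLoggerError"],
               "boom")
  # extra records survive a render/parse round-trip
  expect_identical(parse_document(render_document(doc, 80)), doc)
})

test_that("forwarding sends rendered lines and still writes the native log", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  seen <- character(0)
  activate(hooks = FALSE, log_dir = tmp, log_name = "f.runinfo",
           announce = FALSE, forward_target = function(line) {
             seen <<- c(seen, line)
           })
  path <- emit()
  expect_true(file.exists(path))  # native file still written
  native <- readLines(path)
  expect_identical(seen, native)  # identical rendered lines forwarded
})

test_that("a file path forward target receives the identical rendered lines", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  sink_path <- file.path(tmp, "host-facility.log")
  activate(hooks = FALSE, log_dir = tmp, log_name = "g.runinfo",
           announce = FALSE, forward_target = sink_path)
  path <- emit()
  expect_identical(readLines(sink_path), readLines(path))
})

test_that("an unwritable destination yields one diagnostic, no retry", {
  ri_local_state()
  activate(hooks = FALSE, log_dir = file.path(tempdir(), "no/such/dir"),
           log_name = "y.runinfo", announce = FALSE)
  expect_message(p <- emit(), "failed to write")
  expect_null(p)
  expect_silent(expect_null(emit()))  # emitted is set; no second attempt
})

test_that("the announcement names the written log on the diagnostic stream", {
  ri_local_state()
  tmp <- withr::local_tempdir()
  activate(hooks = FALSE, log_dir = tmp, log_name = "a.runinfo")
  expect_message(emit(), "runinfo: log written to .*a\\.runinfo")
})

test_that("hook installation is idempotent", {
  st <- new.env(parent = emptyenv())
  expect_true(install_termination_hooks(st))
  expect_false(install_termination_hooks(st))  # second call installs nothing
})

test_that("a normal exit writes the log via the exit hook", {
  tmp <- withr::local_tempdir()
  res <- ri_run_child(c(
    sprintf('runinfo::activate(log_dir = "%s")', tmp),
    'cat("work done\n")'
  ))
  expect_identical(res$status, 0L)
  expect_identical(res$stdout, "work done")
  logs <- ri_logs_in(tmp)
  expect_length(logs, 1)
  expect_match(res$stderr, "runinfo: log written to", all = FALSE)
  doc <- parse_document(readLines(file.path(tmp, logs)))
  expect_length(validate_document(doc), 0)
  expect_identical(doc$records$payload[doc$records$tag == "EndStat"], "0")
})

test_that("a TERM-killed child leaves a complete log and dies by signal", {
  tmp <- withr::local_tempdir()
  px <- ri_spawn(ri_sleeper_code(tmp))
  Sys.sleep(2)
  px$signal(tools::SIGTERM)
  px$wait(8000)
  expect_identical(px$get_exit_status(), -15L)  # conventional signal death
  logs <- ri_logs_in(tmp)
  expect_length(logs, 1)
  doc <- parse_document(readLines(file.path(tmp, logs)))
  expect_length(validate_document(doc), 0)
  expect_identical(doc$records$payload[doc$records$tag == "EndStat"],
                   "SIGTERM")
})

test_that("environment variables suppress or redirect a single run", {
  tmp <- withr::local_tempdir()
  res <- ri_run_child(
    c(sprintf('runinfo::activate(log_dir = "%s", enabled = TRUE)', tmp), "invisible(1)"),
    env = c(RUNINFO_SUPPRESS = "1")
  )
  expect_length(ri_logs_in(tmp), 0)  # env suppression beats activation

  redirected <- withr::local_tempdir()
  res2 <- ri_run_child(
    c(sprintf('runinfo::activate(log_dir = "%s")', tmp), "invisible(1)"),
    env = c(RUNINFO_DIR = redirected)
  )
  expect_length(ri_logs_in(tmp), 0)
  expect_length(ri_logs_in(redirected), 1)
})
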