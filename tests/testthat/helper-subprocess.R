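# Subprocess harness: run small instrumented programs under Rscript so
# exit hooks and signal handlers are exercised for real. The child
# inherits this session's library paths so the package resolves from
# non-default libraries.

ri_rscript <- function() file.path(R.home("bin"), "Rscript")

ri_lib_env <- function() {
  paste(.libPaths(), collapse = .Platform$path.sep)
}

ri_child_env <- function(...) {
  c("current", R_LIBS = ri_lib_env(), ...)
}

# Start an instrumented child process; returns the processx process.
ri_spawn <- function(code, env = character(0), args = character(0)) {
  script <- tempfile("runinfo-child-", fileext = ".R")
  writeLines(code, script)
  processx::process$new(
    ri_rscript(), c(script, args),
    stdout = "|", stderr = "|",
    env = do.call(ri_child_env, as.list(env))
  )
}

# Run to completion; returns list(status, stdout, stderr).
ri_run_child <- function(code, env = character(0), args = character(0),
                         timeout = 30000) {
  px <- ri_spawn(code, env = env, args = args)
  px$wait(timeout)
  if (px$is_alive()) {
    px$kill()
    stop("instrumented child timed out")
  }
  list(status = px$get_exit_status(),
       stdout = px$read_all_output_lines(),
       stderr = px$read_all_error_lines())
}

# A child that sleeps (good for TERM/HUP, which R does not intercept).
ri_sleeper_code <- function(dir, secs = 10) {
  c(
    sprintf('runinfo::activate(log_dir = "%s")', dir),
    sprintf("Sys.sleep(%s)", secs)
  )
}

# A child that computes (good for INT: R owns SIGINT during interruptible
# waits such as Sys.sleep, so the handler only sees it between them).
ri_spinner_code <- function(dir) {
  c(
    sprintf('runinfo::activate(log_dir = "%s")', dir),
    "x <- 0",
    "for (i in 1:2e9) x <- x + 1"
  )
}

ri_cli <- function(...) {
  exec <- system.file("exec", "runinfo", package = "runinfo")
  processx::run(ri_rscript(), c(exec, ...), error_on_status = FALSE,
                env = ri_child_env())
}

ri_signal_number <- function(name) {
  switch(name,
    SIGHUP = tools::SIGHUP,
    SIGINT = tools::SIGINT,
    SIGQUIT = tools::SIGQUIT,
    SIGTERM = tools::SIGTERM,
    stop("unknown signal ", name)
  )
}

ri_logs_in <- function(dir) {
  list.files(dir, pattern = "\\.runinfo$")
}
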