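## One-line activation: option resolution with environment-variable
## override, exit-hook and signal-handler installation, once-only emission
## at termination, and program-specified extra-logger callbacks.

.ri_state <- new.env(parent = emptyenv())

RI_OPTION_NAMES <- c("enabled", "log_dir", "log_name", "announce",
                     "forward_target", "module_checksums", "program_version")
RI_ENV_PREFIX <- "RUNINFO_"

#' Default logging options
#'
#' Logging is on by default, writing an auto-named file (see
#' [default_log_filename()]) in the current working directory, announcing
#' the log location on the diagnostic stream, with per-module checksums
#' off.
#'
#' @return Named list of option defaults.
#' @export
default_options <- function() {
  list(enabled = TRUE, log_dir = ".", log_name = "AUTO", announce = TRUE,
       forward_target = NULL, module_checksums = FALSE,
       program_version = NULL)
}

ri_parse_env_flag <- function(value, key) {
  v <- tolower(trimws(value))
  if (v %in% c("1", "true", "yes", "on")) {
    return(TRUE)
  }
  if (v %in% c("0", "false", "no", "off")) {
    return(FALSE)
  }
  warning(sprintf("runinfo: ignoring malformed boolean %s=%s", key, value),
          call. = FALSE)
  NA
}

ri_env_snapshot <- function(env = Sys.getenv()) {
  vals <- as.list(env)
  if (length(vals) == 0L) {
    return(vals)
  }
  vals[startsWith(names(vals), RI_ENV_PREFIX)]
}

ri_merge_layer <- function(opts, layer) {
  unknown <- setdiff(names(layer), RI_OPTION_NAMES)
  if (length(unknown) > 0L) {
    warning("runinfo: ignoring unknown option(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    layer <- layer[setdiff(names(layer), unknown)]
  }
  for (k in names(layer)) {
    opts[[k]] <- layer[[k]]
  }
  opts
}

#' Resolve logging options by precedence
#'
#' Precedence is defaults < each activation layer in order < environment
#' variables. The environment snapshot is the one saved at first
#' activation, applied last and idempotently after every merge, so a
#' single run can be suppressed, enabled or redirected without touching
#' the program.
#'
#' Recognized variables (booleans accept `0/1/true/false/yes/no/on/off`,
#' case-insensitive):
#' \describe{
#'   \item{RUNINFO_SUPPRESS}{truthy value disables logging}
#'   \item{RUNINFO_DIR}{log directory}
#'   \item{RUNINFO_NAME}{log file name (`AUTO` for the default)}
#'   \item{RUNINFO_ANNOUNCE}{announce the log path on the diagnostic stream}
#'   \item{RUNINFO_MODULE_CHECKSUMS}{checksum every loaded module}
#'   \item{RUNINFO_FORWARD}{path of a host logging sink to forward lines to}
#' }
#' Unknown `RUNINFO_*` keys and malformed boolean values produce a
#' diagnostic warning and are ignored, never an error.
#'
#' @param defaults Full option list (see [default_options()]).
#' @param layers List of partial option lists, applied in order
#'   (later layers win).
#' @param env Named list/vector of environment variables (only
#'   `RUNINFO_*` keys are considered).
#' @return The resolved option list.
#' @export
resolve_options <- function(defaults = default_options(), layers = list(),
                            env = list()) {
  opts <- defaults
  for (layer in layers) {
    opts <- ri_merge_layer(opts, layer)
  }
  env <- ri_env_snapshot(env)
  for (key in names(env)) {
    value <- env[[key]]
    switch(key,
      RUNINFO_SUPPRESS = {
        f <- ri_parse_env_flag(value, key)
        if (!is.na(f)) opts$enabled <- !f
      },
      RUNINFO_DIR = opts$log_dir <- value,
      RUNINFO_NAME = opts$log_name <- value,
      RUNINFO_ANNOUNCE = {
        f <- ri_parse_env_flag(value, key)
        if (!is.na(f)) opts$announce <- f
      },
      RUNINFO_MODULE_CHECKSUMS = {
        f <- ri_parse_env_flag(value, key)
        if (!is.na(f)) opts$module_checksums <- f
      },
      RUNINFO_FORWARD = opts$forward_target <- value,
      warning(sprintf("runinfo: unknown environment option %s", key),
              call. = FALSE)
    )
  }
  opts
}

ri_signal_table <- function() {
  nums <- tryCatch(.Call(ri_signal_numbers), error = function(e) NULL)
  if (is.null(nums)) {
    return(integer(0))
  }
  stats::setNames(nums, c("SIGHUP", "SIGINT", "SIGQUIT", "SIGTERM"))
}

ri_signal_name <- function(sig) {
  tbl <- ri_signal_table()
  hit <- names(tbl)[match(sig, tbl)]
  if (length(hit) == 1L && !is.na(hit)) hit else paste0("SIG", sig)
}

## entered from the C signal handler; must never raise back into C
.ri_on_signal <- function(sig) {
  tryCatch(emit(reason = ri_signal_name(sig)), error = function(e) NULL)
  invisible(NULL)
}

#' Install the termination hooks
#'
#' Registers an exit finalizer that writes the log at normal termination,
#' and C-level handlers for the catchable termination signals (`TERM`,
#' `INT`, `HUP`, `QUIT` where the platform defines them; never `KILL`).
#' A handler emits the log, invokes any plain handler the host had
#' installed before activation, then restores the default disposition and
#' re-raises, so the parent observes a true signal death. Installation
#' happens once; repeated calls change nothing. A host that later resets a
#' handler to the default disposition forfeits signal-time logging --
#' accepted behavior.
#'
#' @param state Internal activation state (exposed for testing).
#' @return `TRUE` if hooks were installed by this call, `FALSE` if they
#'   already were, invisibly.
#' @export
install_termination_hooks <- function(state = .ri_state) {
  if (isTRUE(state$hooks_installed)) {
    return(invisible(FALSE))
  }
  reg.finalizer(state, function(e) {
    tryCatch(emit(reason = "exit", state = e), error = function(err) NULL)
  }, onexit = TRUE)
  sigs <- ri_signal_table()
  if (length(sigs) > 0L) {
    .Call(ri_install_handlers, as.integer(sigs),
          function(s) .ri_on_signal(s))
  }
  state$hooks_installed <- TRUE
  invisible(TRUE)
}

#' Activate provenance logging
#'
#' The one line a program needs: `runinfo::activate()`. The first call
#' copies the command-line arguments, records the start time, saves the
#' `RUNINFO_*` environment variables, installs the termination hooks and
#' sets option defaults -- then applies any options given here. Later
#' calls only merge their options over the current ones (later layers
#' win), which lets a shared configuration module set a common baseline
#' that individual programs override. Saved environment variables are
#' re-applied last after every merge and take precedence over everything.
#'
#' @param ... Options by name: `enabled`, `log_dir`, `log_name`
#'   (`"AUTO"` for the default name), `announce`, `forward_target` (a
#'   function of one character-vector argument, or a file path to append
#'   to), `module_checksums`, `program_version`.
#' @param hooks Install termination hooks on first activation (set
#'   `FALSE` only when embedding the logger and managing emission
#'   yourself, e.g. in tests).
#' @return The activation state snapshot, invisibly.
#' @examples
#' \dontrun{
#' runinfo::activate()                       # defaults
#' runinfo::activate(log_dir = "logs", module_checksums = TRUE)
#' }
#' @export
activate <- function(..., hooks = TRUE) {
  layer <- list(...)
  if (length(layer) > 0L &&
      (is.null(names(layer)) || any(!nzchar(names(layer))))) {
    stop("all activation options must be named")
  }
  st <- .ri_state
  if (!isTRUE(st$activated)) {
    st$start_time <- Sys.time()
    st$raw_args <- commandArgs(trailingOnly = FALSE)
    st$argv_copy <- commandArgs(trailingOnly = TRUE)
    st$saved_env <- ri_env_snapshot()
    st$layers <- list()
    st$extra_loggers <- list()
    st$emitted <- FALSE
    st$activated <- TRUE
    if (isTRUE(hooks)) {
      install_termination_hooks(st)
    }
  }
  if (length(layer) > 0L) {
    st$layers <- c(st$layers, list(layer))
  }
  st$resolved <- resolve_options(default_options(), st$layers, st$saved_env)
  invisible(structure(
    list(activated = TRUE, emitted = isTRUE(st$emitted),
         start_time = st$start_time, argv = st$argv_copy,
         options = st$resolved),
    class = "runinfo_activation"
  ))
}

#' Register an extra logger callback
#'
#' The callback runs at emission time, after all standard records, and
#' receives a record appender `function(tag, payload)`; records it appends
#' carry program-chosen tags and are serialized like any other record.
#' Callbacks run in registration order. A callback that raises is caught
#' and replaced by a diagnostic record -- emission always completes.
#'
#' @param callback A function of one argument (the appender).
#' @return Invisibly, the number of registered callbacks.
#' @export
register_extra_logger <- function(callback) {
  if (!is.function(callback)) {
    stop("callback must be a function")
  }
  st <- .ri_state
  st$extra_loggers <- c(st$extra_loggers, list(callback))
  invisible(length(st$extra_loggers))
}

ri_collect_extra_records <- function(callbacks) {
  recs <- list()
  append_record <- function(tag, payload) {
    recs[[length(recs) + 1L]] <<- log_record(tag, payload)
    invisible(NULL)
  }
  for (cb in callbacks) {
    tryCatch(cb(append_record), error = function(e) {
      recs[[length(recs) + 1L]] <<-
        log_record("ExtraLoggerError",
                   paste("callback failed:", conditionMessage(e)))
    })
  }
  recs
}

ri_append_lines <- function(path, lines) {
  con <- file(path, open = "ab")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))),
           con)
}

ri_unique_log_path <- function(dir, filename) {
  path <- file.path(dir, filename)
  if (!file.exists(path)) {
    return(path)
  }
  stem <- sub("\\.runinfo$", "", filename)
  k <- 1L
  repeat {
    cand <- file.path(dir, sprintf("%s-%d.runinfo", stem, k))
    if (!file.exists(cand)) {
      return(cand)
    }
    k <- k + 1L
  }
}

#' Emit the provenance log
#'
#' Called automatically by the exit hook and the signal handlers; callable
#' directly when managing emission manually. The first call (guarded by an
#' interrupt-safe test-and-set, so a signal arriving during emission
#' cannot trigger a second one) snapshots the environment, builds the
#' document, writes it to the configured destination, forwards the
#' rendered lines to the forward target if one is configured, and
#' announces the path on the diagnostic stream. Every subsequent call is a
#' no-op. An unwritable destination produces a single diagnostic message;
#' forwarding is still attempted and the emitted state is still set (no
#' retry storms).
#'
#' @param reason `"exit"` for normal termination, or a signal name such as
#'   `"SIGTERM"`; recorded in `EndStat`.
#' @param state Internal activation state (exposed for testing).
#' @return The written log path invisibly, or `invisible(NULL)` when
#'   nothing was written.
#' @export
emit <- function(reason = "exit", state = .ri_state) {
  if (!isTRUE(state$activated)) {
    return(invisible(NULL))
  }
  if (isTRUE(state$emitted) || !isTRUE(.Call(ri_once))) {
    state$emitted <- TRUE
    return(invisible(NULL))
  }
  state$emitted <- TRUE
  opts <- state$resolved
  if (!isTRUE(opts$enabled)) {
    return(invisible(NULL))
  }

  end_time <- Sys.time()
  status <- if (identical(reason, "exit")) 0L else reason
  window <- finalize_window(state$start_time, end_time, status)
  main_path <- ri_script_path(state$raw_args)
  program <- snapshot_program(state$argv_copy, main_path,
                              opts$program_version)
  doc <- build_document(
    modules = snapshot_modules(with_checksums = isTRUE(opts$module_checksums)),
    search_path = snapshot_search_path(),
    system = snapshot_system(),
    interpreter = snapshot_interpreter(),
    user = snapshot_user(),
    program = program,
    window = window,
    extra_records = ri_collect_extra_records(state$extra_loggers)
  )

  filename <- opts$log_name
  if (identical(filename, "AUTO")) {
    prog_name <- if (identical(program$name, RI_UNKNOWN)) "R" else program$name
    filename <- default_log_filename(prog_name, state$start_time)
  }
  path <- ri_unique_log_path(opts$log_dir, filename)

  written <- tryCatch({
    suppressWarnings(write_document(doc, path))
    TRUE
  }, error = function(e) {
    message("runinfo: failed to write log at ", path, ": ",
            conditionMessage(e))
    FALSE
  })

  target <- opts$forward_target
  if (!is.null(target)) {
    lines <- strsplit(render_document(doc), "\n", fixed = TRUE)[[1]]
    tryCatch({
      if (is.function(target)) {
        for (ln in lines) target(ln)
      } else {
        ri_append_lines(as.character(target), lines)
      }
    }, error = function(e) {
      message("runinfo: failed to forward log: ", conditionMessage(e))
    })
  }

  if (written && isTRUE(opts$announce)) {
    message("runinfo: log written to ", path)
  }
  invisible(if (written) path else NULL)
}

## test support: return the logger to its pre-activation state
.ri_reset <- function() {
  st <- .ri_state
  st$activated <- FALSE
  st$emitted <- FALSE
  st$layers <- list()
  st$extra_loggers <- list()
  st$resolved <- NULL
  st$hooks_installed <- isTRUE(st$hooks_installed)
  .Call(ri_once_reset)
  invisible(NULL)
}
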