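## Environment capture: typed snapshots of the running program's state.
## Every snapshot_* function is infallible by contract -- introspection
## failures produce "UNKNOWN" sentinels, never conditions that could abort
## the host program at emission time.

#' Module record
#'
#' One loaded library module: name, version, file location and checksum.
#' Unobtainable fields hold `"UNKNOWN"`; a module with no on-disk source
#' has path `"BUILTIN"`.
#'
#' @param name Module identifier; non-empty, no whitespace.
#' @param version Version string or `"UNKNOWN"`.
#' @param path Absolute file location or `"BUILTIN"`.
#' @param checksum Lowercase hex digest or `"UNKNOWN"`.
#' @return A `runinfo_module` object.
#' @export
module_record <- function(name, version = RI_UNKNOWN, path = RI_BUILTIN,
                          checksum = RI_UNKNOWN) {
  name <- as.character(name)
  if (length(name) != 1L || is.na(name) || !nzchar(name) || grepl("\\s", name)) {
    stop("module name must be a non-empty string without whitespace")
  }
  if (!is_digest_or_unknown(checksum)) {
    stop("checksum must be 'UNKNOWN' or a ", RI_DIGEST_NCHAR,
         "-char lowercase hex digest")
  }
  structure(
    list(name = name, version = as.character(version),
         path = as.character(path), checksum = as.character(checksum)),
    class = "runinfo_module"
  )
}

## registry of loaded namespaces, the R analog of a loaded-module table
loaded_module_registry <- function() {
  nss <- loadedNamespaces()
  version <- vapply(nss, function(ns) {
    tryCatch(as.character(getNamespaceVersion(ns)), error = function(e) RI_UNKNOWN)
  }, character(1))
  path <- vapply(nss, function(ns) {
    tryCatch(find.package(ns), error = function(e) NA_character_)
  }, character(1))
  data.frame(name = nss, version = version, path = path,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Snapshot the loaded modules
#'
#' Produces one [module_record()] per distinct loaded module, sorted by
#' name. Called at emission time so late-loaded modules are included. Module
#' checksums are computed only on request: hashing every loaded library
#' takes time most runs do not want to spend, so the default leaves the
#' checksum field `"UNKNOWN"`.
#'
#' For an R package the recorded location is the installed package
#' directory and the checksum target is its `DESCRIPTION` file (the one
#' member every installed package is guaranteed to have).
#'
#' @param registry A data frame with columns `name`, `version`, `path`
#'   (path `NA` for builtins). Defaults to the loaded-namespace table.
#' @param with_checksums Compute per-module checksums?
#' @return List of `runinfo_module`, sorted by name.
#' @export
snapshot_modules <- function(registry = loaded_module_registry(),
                             with_checksums = FALSE) {
  registry <- as.data.frame(registry, stringsAsFactors = FALSE)
  if (nrow(registry) == 0L) {
    return(list())
  }
  registry <- registry[!duplicated(registry$name), , drop = FALSE]
  registry <- registry[order(registry$name, method = "radix"), , drop = FALSE]
  lapply(seq_len(nrow(registry)), function(i) {
    name <- registry$name[[i]]
    version <- registry$version[[i]]
    if (is.na(version) || !nzchar(version)) version <- RI_UNKNOWN
    path <- registry$path[[i]]
    if (is.na(path) || !nzchar(path)) path <- RI_BUILTIN
    checksum <- RI_UNKNOWN
    if (isTRUE(with_checksums) && !identical(path, RI_BUILTIN)) {
      target <- if (dir.exists(path)) file.path(path, "DESCRIPTION") else path
      checksum <- checksum_file(target)
    }
    module_record(name, version, path, checksum)
  })
}

#' Snapshot the module search path
#'
#' Captures the ordered directory list the runtime consults to locate
#' library modules, exactly as reported: order preserved, duplicates kept.
#'
#' @param entries Character vector of directories; defaults to [.libPaths()].
#' @return A `runinfo_search_path` object.
#' @export
snapshot_search_path <- function(entries = .libPaths()) {
  structure(list(entries = as.character(entries)),
            class = "runinfo_search_path")
}

#' Processor record
#'
#' @param index Non-negative processor index.
#' @param attributes Named character vector (model, cores, clock speed where
#'   discoverable); never empty -- an unenumerable processor gets
#'   `c(model = "UNKNOWN")`.
#' @return A `runinfo_processor` object.
#' @export
processor_record <- function(index, attributes = c(model = RI_UNKNOWN)) {
  index <- as.integer(index)
  stopifnot(length(index) == 1L, !is.na(index), index >= 0L)
  attributes <- vapply(attributes, as.character, character(1))
  if (length(attributes) == 0L || is.null(names(attributes)) ||
      any(!nzchar(names(attributes)))) {
    attributes <- c(model = RI_UNKNOWN)
  }
  structure(list(index = index, attributes = attributes),
            class = "runinfo_processor")
}

## /proc/cpuinfo -> list of named attribute vectors, or NULL off-Linux
read_cpuinfo <- function(path = "/proc/cpuinfo") {
  if (!file.exists(path)) {
    return(NULL)
  }
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) NULL)
  if (is.null(lines)) {
    return(NULL)
  }
  blocks <- split(lines, cumsum(!nzchar(lines)))
  keep <- c("model name" = "model", "cpu cores" = "cores",
            "cpu MHz" = "mhz", "cache size" = "cache")
  out <- list()
  for (bl in blocks) {
    bl <- bl[nzchar(bl)]
    if (!any(grepl("^processor\\s*:", bl))) next
    attrs <- character(0)
    for (ln in bl) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2L) next
      key <- trimws(kv[[1]])
      if (key %in% names(keep)) {
        attrs[[keep[[key]]]] <- trimws(paste(kv[-1], collapse = ":"))
      }
    }
    out[[length(out) + 1L]] <- attrs
  }
  if (length(out) == 0L) NULL else out
}

read_total_memory <- function(path = "/proc/meminfo") {
  if (!file.exists(path)) {
    return(NA_real_)
  }
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  m <- grep("^MemTotal:", lines, value = TRUE)
  if (length(m) == 0L) {
    return(NA_real_)
  }
  kb <- suppressWarnings(as.numeric(gsub("[^0-9]", "", m[[1]])))
  if (is.na(kb)) NA_real_ else kb * 1024
}

#' System information constructor
#'
#' @param os_name,node_name,os_release,os_version,machine OS identification
#'   strings (unobtainable values become `"UNKNOWN"`).
#' @param processors List of [processor_record()] or of named attribute
#'   vectors (indices are assigned 0..n-1 in order).
#' @param total_memory_bytes Total physical memory, or `NA` when unknown.
#' @return A `runinfo_system` object.
#' @export
system_info <- function(os_name, node_name, os_release, os_version, machine,
                        processors, total_memory_bytes = NA_real_) {
  procs <- lapply(seq_along(processors), function(i) {
    p <- processors[[i]]
    if (inherits(p, "runinfo_processor")) {
      processor_record(i - 1L, p$attributes)
    } else {
      processor_record(i - 1L, p)
    }
  })
  if (length(procs) == 0L) {
    procs <- list(processor_record(0L))
  }
  str1 <- function(x) {
    x <- as.character(x)
    if (length(x) != 1L || is.na(x) || !nzchar(x)) RI_UNKNOWN else x
  }
  structure(
    list(os_name = str1(os_name), node_name = str1(node_name),
         os_release = str1(os_release), os_version = str1(os_version),
         machine = str1(machine), processors = procs,
         total_memory_bytes = as.numeric(total_memory_bytes)),
    class = "runinfo_system"
  )
}

#' Snapshot operating system and processor information
#'
#' OS identity comes from the platform identification facility
#' ([Sys.info()]); processors are enumerated from the per-processor table
#' where the platform exposes one (`/proc/cpuinfo`), otherwise a single
#' aggregate record at index 0 is emitted. Nothing here can raise:
#' unobtainable attributes become `"UNKNOWN"`.
#'
#' @param info Named vector in the shape of [Sys.info()] (injectable for
#'   testing).
#' @param processors Optional list of attribute vectors overriding
#'   enumeration.
#' @param total_memory_bytes Optional override for the memory probe.
#' @return A `runinfo_system` object.
#' @export
snapshot_system <- function(info = Sys.info(), processors = NULL,
                            total_memory_bytes = NULL) {
  get1 <- function(key) {
    v <- tryCatch(info[[key]], error = function(e) NA_character_)
    if (is.null(v)) NA_character_ else v
  }
  if (is.null(processors)) {
    processors <- read_cpuinfo()
    if (is.null(processors)) {
      nc <- tryCatch(parallel::detectCores(), error = function(e) NA_integer_)
      processors <- list(c(
        model = RI_UNKNOWN,
        logical_cores = if (is.na(nc)) RI_UNKNOWN else as.character(nc)
      ))
    }
  }
  if (is.null(total_memory_bytes)) {
    total_memory_bytes <- read_total_memory()
  }
  system_info(get1("sysname"), get1("nodename"), get1("release"),
              get1("version"), get1("machine"), processors,
              total_memory_bytes)
}

#' Interpreter information constructor
#'
#' @param executable_path Interpreter binary path (non-empty).
#' @param version Interpreter version string.
#' @param checksum Digest of the interpreter binary or `"UNKNOWN"`.
#' @param libc_version,libc_checksum C runtime library version and digest,
#'   `"UNKNOWN"` where the platform exposes nothing.
#' @return A `runinfo_interpreter` object.
#' @export
interpreter_info <- function(executable_path, version,
                             checksum = RI_UNKNOWN,
                             libc_version = RI_UNKNOWN,
                             libc_checksum = RI_UNKNOWN) {
  stopifnot(is.character(executable_path), nzchar(executable_path))
  if (!is_digest_or_unknown(checksum) || !is_digest_or_unknown(libc_checksum)) {
    stop("checksums must be 'UNKNOWN' or lowercase hex digests")
  }
  structure(
    list(executable_path = executable_path, version = as.character(version),
         checksum = checksum, libc_version = as.character(libc_version),
         libc_checksum = libc_checksum),
    class = "runinfo_interpreter"
  )
}

ri_r_executable <- function() {
  cand <- file.path(R.home("bin"), "exec", "R")
  if (file.exists(cand)) {
    return(cand)
  }
  file.path(R.home("bin"), "R")
}

## best-effort C-library identification; inherently approximate (static
## linking and non-glibc platforms report UNKNOWN)
ri_libc <- function() {
  version <- tryCatch(.Call(ri_libc_version), error = function(e) NULL)
  if (is.null(version) || !nzchar(version)) version <- RI_UNKNOWN
  path <- NA_character_
  maps <- "/proc/self/maps"
  if (file.exists(maps)) {
    lines <- tryCatch(readLines(maps, warn = FALSE), error = function(e) character(0))
    hit <- grep("/libc[.-][^/]*so", lines, value = TRUE)
    if (length(hit) > 0L) {
      path <- sub("^[^/]*", "", hit[[1]])
    }
  }
  checksum <- if (is.na(path)) RI_UNKNOWN else checksum_file(path)
  list(version = version, checksum = checksum)
}

#' Snapshot the interpreter
#'
#' Records the R binary's path, version and checksum, plus a best-effort
#' identification of the C runtime library it uses (version from the glibc
#' configuration string, checksum of the mapped `libc` shared object). On
#' platforms exposing neither, the libc fields hold `"UNKNOWN"`.
#'
#' @param executable Path to the interpreter binary (injectable for tests).
#' @return A `runinfo_interpreter` object.
#' @export
snapshot_interpreter <- function(executable = ri_r_executable()) {
  libc <- tryCatch(ri_libc(),
                   error = function(e) list(version = RI_UNKNOWN,
                                            checksum = RI_UNKNOWN))
  interpreter_info(
    executable_path = executable,
    version = R.version.string,
    checksum = checksum_file(executable),
    libc_version = libc$version,
    libc_checksum = libc$checksum
  )
}

#' User context constructor
#'
#' Real identities are stored only when they differ from the effective
#' ones (they are logged "if different").
#'
#' @param effective_user `id(name)` string for the effective user.
#' @param effective_groups Character vector of `id(name)` strings, order as
#'   reported by the platform.
#' @param real_user,real_groups As above, or `NULL` when identical to the
#'   effective identities.
#' @return A `runinfo_user` object.
#' @export
user_context <- function(effective_user, effective_groups,
                         real_user = NULL, real_groups = NULL) {
  structure(
    list(effective_user = as.character(effective_user),
         real_user = if (is.null(real_user)) NULL else as.character(real_user),
         effective_groups = as.character(effective_groups),
         real_groups = if (is.null(real_groups)) NULL else as.character(real_groups)),
    class = "runinfo_user"
  )
}

ri_user_ids <- function() {
  tryCatch(.Call(ri_user_info), error = function(e) NULL)
}

#' Snapshot user and group identities
#'
#' Effective identities are always present; real identities only when they
#' differ (privilege switching). Platforms without user/group notions yield
#' `"UNKNOWN"` effective entries.
#'
#' @param ids Identity list as returned by the platform probe (injectable
#'   for testing setuid-style mismatches).
#' @return A `runinfo_user` object.
#' @export
snapshot_user <- function(ids = ri_user_ids()) {
  if (is.null(ids)) {
    return(user_context(RI_UNKNOWN, RI_UNKNOWN))
  }
  fmt <- function(id, name) sprintf("%d(%s)", as.integer(id), name)
  effective_user <- fmt(ids$euid, ids$euname)
  real_user <- if (!identical(as.integer(ids$ruid), as.integer(ids$euid))) {
    fmt(ids$ruid, ids$runame)
  }
  supp <- if (length(ids$groups) > 0L) {
    mapply(fmt, ids$groups, ids$group_names, USE.NAMES = FALSE)
  } else {
    character(0)
  }
  effective_groups <- c(fmt(ids$egid, ids$egname), supp)
  real_groups <- if (!identical(as.integer(ids$rgid), as.integer(ids$egid))) {
    c(fmt(ids$rgid, ids$rgname), supp)
  }
  user_context(effective_user, effective_groups, real_user, real_groups)
}

#' Program identity constructor / snapshot
#'
#' Splits the main program path into directory and name, checksums the
#' program file, and freezes the activation-time copy of the command-line
#' arguments (immune to later mutation by the host program).
#'
#' @param argv Character vector: the argument copy made at activation time.
#' @param main_path Path of the main program file, or `NA` when unknown
#'   (interactive sessions).
#' @param declared_version Program-declared version string, or `NULL` for
#'   `"UNKNOWN"`.
#' @return A `runinfo_program` object.
#' @export
snapshot_program <- function(argv, main_path, declared_version = NULL) {
  argv <- as.character(argv)
  if (length(main_path) != 1L || is.na(main_path) || !nzchar(main_path)) {
    directory <- RI_UNKNOWN
    name <- RI_UNKNOWN
    checksum <- RI_UNKNOWN
  } else {
    directory <- dirname(main_path)
    name <- basename(main_path)
    checksum <- checksum_file(main_path)
  }
  if (is.null(declared_version) || is.na(declared_version) ||
      !nzchar(declared_version)) {
    declared_version <- RI_UNKNOWN
  }
  structure(
    list(directory = directory, name = name,
         declared_version = as.character(declared_version),
         checksum = checksum, argv = argv, arg_count = length(argv)),
    class = "runinfo_program"
  )
}

## main script path for Rscript-launched programs (--file=... argument)
ri_script_path <- function(raw_args = commandArgs(trailingOnly = FALSE)) {
  hit <- grep("^--file=", raw_args, value = TRUE)
  if (length(hit) == 0L) {
    return(NA_character_)
  }
  sub("^--file=", "", hit[[1]])
}

#' Finalize the execution window
#'
#' @param start,end Timezone-aware timestamps (`POSIXct`); `end >= start`
#'   except under clock skew, which clamps elapsed to 0 and attaches a
#'   warning note.
#' @param status Integer exit status for normal exits, or a signal name
#'   string (e.g. `"SIGTERM"`) for signal-triggered termination, preserved
#'   verbatim.
#' @return A `runinfo_window` with fields `start`, `end`,
#'   `elapsed_seconds`, `exit_status`, and `warning` (`NULL` unless skew
#'   was detected).
#' @export
finalize_window <- function(start, end, status) {
  start <- as.POSIXct(start)
  end <- as.POSIXct(end)
  warning_note <- NULL
  elapsed <- as.numeric(difftime(end, start, units = "secs"))
  if (elapsed < 0) {
    warning_note <- "end precedes start (clock skew); elapsed clamped to 0"
    elapsed <- 0
  }
  if (!is.character(status)) {
    status <- as.integer(status)
  }
  structure(
    list(start = start, end = end, elapsed_seconds = elapsed,
         exit_status = status, warning = warning_note),
    class = "runinfo_window"
  )
}
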