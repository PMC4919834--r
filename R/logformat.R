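## The .runinfo log format: `TAG: payload` lines, long payloads wrapped at
## single-space boundaries onto continuation lines beginning "+ ". UTF-8,
## LF line endings, bit-exact. Two META header records (format-version,
## hash-algorithm) make every log self-describing.

RI_TAG_RE <- "^[A-Za-z][A-Za-z0-9-]*$"

## canonical section order; PROC covers PROC0..PROCn, extras come last
RI_TAG_ORDER <- c("MODULE", "INC", "UNAME", "PROC", "INTERP", "INTERPVer",
                  "INTERPSum", "LIBC", "LIBCSum", "User", "Group", "ProgDir",
                  "Program", "Version", "ProgSUM", "Args", "Start", "End",
                  "Elapsed", "EndStat")
RI_REPEATABLE <- c("MODULE", "INC", "Group")
RI_MANDATORY_SINGLETONS <- setdiff(RI_TAG_ORDER, c(RI_REPEATABLE, "PROC"))

ri_tag_rank <- function(tag) {
  r <- match(tag, RI_TAG_ORDER)
  r[grepl("^PROC[0-9]+$", tag)] <- match("PROC", RI_TAG_ORDER)
  r[is.na(r)] <- length(RI_TAG_ORDER) + 1L
  r
}

#' Log record
#'
#' One tagged record of a provenance log. The payload is a single logical
#' line; on disk it may be wrapped over continuation lines.
#'
#' @param tag Token matching `[A-Za-z][A-Za-z0-9-]*`.
#' @param payload Single-line string (no newlines).
#' @return A `runinfo_record` object.
#' @export
log_record <- function(tag, payload = "") {
  tag <- as.character(tag)
  payload <- as.character(payload)
  if (length(tag) != 1L || !grepl(RI_TAG_RE, tag)) {
    stop("invalid record tag: ", deparse(tag))
  }
  if (length(payload) != 1L || is.na(payload) || grepl("[\r\n]", payload)) {
    stop("payload must be a single line")
  }
  structure(list(tag = tag, payload = payload), class = "runinfo_record")
}

#' Log document
#'
#' An ordered sequence of tagged records plus the self-describing header
#' fields, forming one execution's provenance log.
#'
#' @param records A data frame with character columns `tag` and `payload`,
#'   or a list of [log_record()] objects.
#' @param format_version Log format version written to the `META` header.
#' @param hash_algorithm Hash algorithm named in the `META` header.
#' @return A `runinfo_document` object.
#' @export
log_document <- function(records = NULL,
                         format_version = RI_FORMAT_VERSION,
                         hash_algorithm = RI_HASH_ALGORITHM) {
  if (is.null(records)) {
    records <- data.frame(tag = character(0), payload = character(0),
                          stringsAsFactors = FALSE)
  } else if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      tag = vapply(records, function(r) r$tag, character(1)),
      payload = vapply(records, function(r) r$payload, character(1)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(records), all(c("tag", "payload") %in% names(records)))
  records <- data.frame(tag = as.character(records$tag),
                        payload = as.character(records$payload),
                        stringsAsFactors = FALSE)
  bad <- !grepl(RI_TAG_RE, records$tag)
  if (any(bad)) {
    stop("invalid record tag(s): ", paste(unique(records$tag[bad]), collapse = ", "))
  }
  rownames(records) <- NULL
  structure(
    list(format_version = as.character(format_version),
         hash_algorithm = as.character(hash_algorithm),
         records = records),
    class = "runinfo_document"
  )
}

#' @export
print.runinfo_document <- function(x, ...) {
  cat(sprintf("<runinfo log: format %s, hash %s, %d records>\n",
              x$format_version, x$hash_algorithm, nrow(x$records)))
  invisible(x)
}

## ---- field quoting -------------------------------------------------------

## quote a field when it contains spaces, quotes, or is empty
ri_quote_field <- function(x) {
  need <- !nzchar(x) | grepl('[ "\\\\]', x)
  esc <- gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  ifelse(need, paste0('"', esc, '"'), x)
}

ri_quote_always <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

## quote-aware whitespace tokenizer (inverse of ri_quote_field)
ri_split_fields <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  in_quote <- FALSE
  has_token <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (in_quote) {
      if (ch == "\\" && i < n) {
        buf <- c(buf, chars[[i + 1L]])
        i <- i + 2L
        next
      }
      if (ch == '"') {
        in_quote <- FALSE
      } else {
        buf <- c(buf, ch)
      }
    } else if (ch == '"') {
      in_quote <- TRUE
      has_token <- TRUE
    } else if (ch == " ") {
      if (has_token) {
        out <- c(out, paste(buf, collapse = ""))
        buf <- character(0)
        has_token <- FALSE
      }
    } else {
      buf <- c(buf, ch)
      has_token <- TRUE
    }
    i <- i + 1L
  }
  if (in_quote) {
    stop("unterminated quoted field in: ", s)
  }
  if (has_token) {
    out <- c(out, paste(buf, collapse = ""))
  }
  out
}

## ---- naming --------------------------------------------------------------

#' Default log file name
#'
#' The default name embeds the instrumented program's name and a local-time
#' stamp so separate runs are distinguishable:
#' `<program>.<YYYYMMDD-HHMMSS>.runinfo`. Path separators in the program
#' name are replaced by underscores.
#'
#' @param program_name Non-empty program name.
#' @param timestamp Time of the run (local time is used in the stamp).
#' @return The file name (no directory component).
#' @examples
#' default_log_filename("simple.pl", as.POSIXct("2016-06-24 10:11:12"))
#' @export
default_log_filename <- function(program_name, timestamp = Sys.time()) {
  program_name <- as.character(program_name)
  if (length(program_name) != 1L || is.na(program_name) || !nzchar(program_name)) {
    stop("program_name must be non-empty")
  }
  program_name <- gsub("[/\\\\]", "_", program_name)
  sprintf("%s.%s.runinfo", program_name, format(timestamp, "%Y%m%d-%H%M%S"))
}

## ---- document assembly ---------------------------------------------------

ri_format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")

#' Build a canonical log document from environment snapshots
#'
#' Assembles the snapshots taken at emission time into a document in the
#' canonical record order: `MODULE*`, `INC*`, `UNAME`, `PROC0..n`,
#' `INTERP`, `INTERPVer`, `INTERPSum`, `LIBC`, `LIBCSum`, `User`,
#' `Group*`, `ProgDir`, `Program`, `Version`, `ProgSUM`, `Args`, `Start`,
#' `End`, `Elapsed`, `EndStat`, then any program-specified extra records.
#' The `Args` payload is the argument count followed by each argument
#' individually quoted.
#'
#' @param modules List of [module_record()].
#' @param search_path A [snapshot_search_path()] result.
#' @param system A [system_info()] object.
#' @param interpreter An [interpreter_info()] object.
#' @param user A [user_context()] object.
#' @param program A [snapshot_program()] result.
#' @param window A [finalize_window()] result.
#' @param extra_records List of [log_record()] (or `list(tag=, payload=)`)
#'   appended after the standard records.
#' @param format_version,hash_algorithm Header fields.
#' @return A `runinfo_document`.
#' @export
build_document <- function(modules, search_path, system, interpreter, user,
                           program, window, extra_records = list(),
                           format_version = RI_FORMAT_VERSION,
                           hash_algorithm = RI_HASH_ALGORITHM) {
  tags <- character(0)
  payloads <- character(0)
  add <- function(tag, payload) {
    tags[[length(tags) + 1L]] <<- tag
    payloads[[length(payloads) + 1L]] <<- payload
  }

  for (m in modules) {
    add("MODULE", paste(m$name, ri_quote_field(m$version),
                        ri_quote_field(m$path), m$checksum))
  }
  for (e in search_path$entries) {
    add("INC", e)
  }
  add("UNAME", paste(system$os_name, system$node_name, system$os_release,
                     system$os_version, system$machine))
  for (p in system$processors) {
    attrs <- p$attributes
    if (p$index == 0L && !is.na(system$total_memory_bytes)) {
      attrs <- c(attrs,
                 `total-memory-bytes` = format(system$total_memory_bytes,
                                               scientific = FALSE))
    }
    add(paste0("PROC", p$index),
        paste(paste0(names(attrs), "=", ri_quote_field(unname(attrs))),
              collapse = " "))
  }
  add("INTERP", interpreter$executable_path)
  add("INTERPVer", interpreter$version)
  add("INTERPSum", interpreter$checksum)
  add("LIBC", interpreter$libc_version)
  add("LIBCSum", interpreter$libc_checksum)
  u <- user$effective_user
  if (!is.null(user$real_user)) {
    u <- paste0(u, " real=", user$real_user)
  }
  add("User", u)
  for (g in user$effective_groups) {
    add("Group", g)
  }
  if (!is.null(user$real_groups)) {
    add("Group", paste("real:", paste(user$real_groups, collapse = " ")))
  }
  add("ProgDir", program$directory)
  add("Program", program$name)
  add("Version", program$declared_version)
  add("ProgSUM", program$checksum)
  args_payload <- as.character(program$arg_count)
  if (program$arg_count > 0L) {
    args_payload <- paste(args_payload,
                          paste(ri_quote_always(program$argv), collapse = " "))
  }
  add("Args", args_payload)
  add("Start", ri_format_time(window$start))
  add("End", ri_format_time(window$end))
  add("Elapsed", sprintf("%.3f", window$elapsed_seconds))
  add("EndStat", as.character(window$exit_status))
  if (!is.null(window$warning)) {
    add("LogNote", window$warning)
  }
  for (r in extra_records) {
    add(r$tag, r$payload)
  }

  log_document(data.frame(tag = tags, payload = payloads,
                          stringsAsFactors = FALSE),
               format_version = format_version,
               hash_algorithm = hash_algorithm)
}

## ---- rendering -----------------------------------------------------------

## wrap one record; break only at isolated single spaces so that rejoining
## continuation lines with a single space reproduces the payload exactly
ri_wrap_record <- function(tag, payload, width) {
  head <- paste0(tag, ":")
  if (!nzchar(payload)) {
    return(head)
  }
  full <- paste(head, payload)
  if (!is.finite(width) || nchar(full) <= width) {
    return(full)
  }
  ## payloads with leading/trailing blanks or multi-space-only content are
  ## emitted unbroken: wrapping them could not round-trip
  if (grepl("^\\s|\\s$", payload)) {
    return(full)
  }
  segs <- strsplit(payload, "(?<! ) (?! )", perl = TRUE)[[1]]
  lines <- character(0)
  cur <- head
  bare <- TRUE
  for (seg in segs) {
    cand <- paste(cur, seg)
    if (bare || nchar(cand) <= width) {
      cur <- cand
      bare <- FALSE
    } else {
      lines <- c(lines, cur)
      cur <- paste("+", seg)
    }
  }
  c(lines, cur)
}

#' Render a log document to text
#'
#' Each record is rendered as `TAG: payload`; at a finite width, long
#' payloads are wrapped at whitespace onto continuation lines beginning
#' `"+ "`. Rendering then parsing yields the original document. Output is
#' UTF-8 with LF line endings and ends with a newline.
#'
#' @param doc A `runinfo_document`.
#' @param width Maximum line width, or `Inf` for no wrapping. Single tokens
#'   longer than the width are emitted unbroken.
#' @return A single string.
#' @export
render_document <- function(doc, width = 80L) {
  stopifnot(inherits(doc, "runinfo_document"))
  lines <- c(
    paste("META: format-version", doc$format_version),
    paste("META: hash-algorithm", doc$hash_algorithm)
  )
  for (i in seq_len(nrow(doc$records))) {
    lines <- c(lines, ri_wrap_record(doc$records$tag[[i]],
                                     doc$records$payload[[i]], width))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a rendered log document to a file
#'
#' Bit-exact write (UTF-8, LF) via a temporary file in the target
#' directory followed by an atomic rename, so a log either exists
#' completely or not at all.
#'
#' @param doc A `runinfo_document`.
#' @param path Destination file path.
#' @param width Wrap width passed to [render_document()].
#' @return The path, invisibly.
#' @export
write_document <- function(doc, path, width = 80L) {
  text <- render_document(doc, width)
  tmp <- file.path(dirname(path),
                   sprintf(".runinfo-tmp-%d-%s", Sys.getpid(), basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeBin(charToRaw(enc2utf8(text)), con)
  close(con)
  if (!file.rename(tmp, path)) {
    stop("cannot move log into place at ", path)
  }
  invisible(path)
}

## ---- parsing -------------------------------------------------------------

ri_parse_error <- function(line, msg) {
  stop(structure(
    class = c("runinfo_parse_error", "error", "condition"),
    list(message = sprintf("line %d: %s", line, msg), call = NULL,
         line = line)
  ))
}

#' Parse a provenance log
#'
#' Inverse of [render_document()]: continuation lines (`"+ "` prefix) are
#' joined to their predecessor with a single space, record order is
#' preserved, and leading `META` header records populate the document's
#' `format_version` / `hash_algorithm` fields. Unknown tags are preserved,
#' not rejected -- program-specified tags are open-ended.
#'
#' @param text A single string (possibly multi-line) or a character vector
#'   of lines.
#' @return A `runinfo_document`.
#' @section Errors: a continuation line with no predecessor, or a line
#'   without a `TAG:` separator, raises a `runinfo_parse_error` naming the
#'   line number.
#' @export
parse_document <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  ## drop trailing blank line(s) produced by the final newline
  while (length(text) > 0L && !nzchar(text[[length(text)]])) {
    text <- text[-length(text)]
  }
  tags <- character(0)
  payloads <- character(0)
  for (i in seq_along(text)) {
    line <- text[[i]]
    if (startsWith(line, "+ ") || identical(line, "+")) {
      if (length(tags) == 0L) {
        ri_parse_error(i, "continuation line with no preceding record")
      }
      payloads[[length(payloads)]] <-
        paste(payloads[[length(payloads)]], substring(line, 3L))
      next
    }
    m <- regmatches(line,
                    regexec("^([A-Za-z][A-Za-z0-9-]*):(?: (.*))?$", line))[[1]]
    if (length(m) == 0L) {
      ri_parse_error(i, paste0("not a 'TAG: payload' line: ", deparse(line)))
    }
    tags <- c(tags, m[[2]])
    payloads <- c(payloads, if (is.na(m[[3]])) "" else m[[3]])
  }

  format_version <- RI_FORMAT_VERSION
  hash_algorithm <- RI_HASH_ALGORITHM
  while (length(tags) > 0L && tags[[1]] == "META") {
    kv <- regmatches(payloads[[1]],
                     regexec("^(format-version|hash-algorithm) (\\S+)$",
                             payloads[[1]]))[[1]]
    if (length(kv) == 0L) break
    if (kv[[2]] == "format-version") format_version <- kv[[3]]
    if (kv[[2]] == "hash-algorithm") hash_algorithm <- kv[[3]]
    tags <- tags[-1]
    payloads <- payloads[-1]
  }

  log_document(data.frame(tag = tags, payload = payloads,
                          stringsAsFactors = FALSE),
               format_version = format_version,
               hash_algorithm = hash_algorithm)
}

#' Parse a MODULE record payload
#'
#' Splits the payload into its four whitespace-separated fields (name,
#' version, path, checksum); fields containing spaces are rendered quoted
#' and are unquoted here.
#'
#' @param payload Payload string of a `MODULE` record.
#' @return A [module_record()].
#' @export
parse_module_payload <- function(payload) {
  fields <- ri_split_fields(payload)
  if (length(fields) != 4L) {
    stop("MODULE payload must have 4 fields, got ", length(fields),
         ": ", payload)
  }
  module_record(fields[[1]], fields[[2]], fields[[3]], fields[[4]])
}

## ---- canonical-order validation ------------------------------------------

#' Validate a log document against the canonical layout
#'
#' Checks record ordering (the fixed section order, with program-specified
#' tags last), presence and uniqueness of the mandatory singleton tags,
#' contiguous `PROC` indices starting at 0, and well-formed `MODULE`
#' payloads.
#'
#' @param doc A `runinfo_document`.
#' @return Character vector of problems; empty when the document is valid.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "runinfo_document"))
  problems <- character(0)
  tags <- doc$records$tag

  ranks <- ri_tag_rank(tags)
  if (is.unsorted(ranks)) {
    bad <- which(diff(ranks) < 0)[1] + 1L
    problems <- c(problems,
                  sprintf("record %d (%s) out of canonical order",
                          bad, tags[[bad]]))
  }
  for (tg in RI_MANDATORY_SINGLETONS) {
    n <- sum(tags == tg)
    if (n == 0L) {
      problems <- c(problems, paste0("missing mandatory tag ", tg))
    } else if (n > 1L) {
      problems <- c(problems, paste0("tag ", tg, " repeated ", n, " times"))
    }
  }
  if (!any(tags == "INC")) {
    problems <- c(problems, "missing mandatory tag INC")
  }
  if (!any(tags == "Group")) {
    problems <- c(problems, "missing mandatory tag Group")
  }
  proc_idx <- sort(as.integer(sub("^PROC", "", grep("^PROC[0-9]+$", tags,
                                                    value = TRUE))))
  if (length(proc_idx) == 0L) {
    problems <- c(problems, "missing processor records (PROC0..)")
  } else if (!identical(proc_idx, seq(0L, length(proc_idx) - 1L))) {
    problems <- c(problems, "PROC indices are not contiguous from 0")
  }
  for (p in doc$records$payload[tags == "MODULE"]) {
    ok <- tryCatch({
      parse_module_payload(p)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      problems <- c(problems, paste0("malformed MODULE payload: ", p))
    }
  }
  problems
}
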