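## Classified diff of two parsed provenance logs: which environment
## differences might affect (or explain) differing results between runs.

RI_DIFF_CATEGORIES <- c("module-added", "module-removed", "module-version",
                        "module-checksum", "interpreter", "system",
                        "search-path", "user", "program", "args",
                        "exit-status", "extra")

RI_DEFAULT_IGNORE <- c("Start", "End", "Elapsed")

ri_tag_diff_category <- function(tag) {
  if (grepl("^PROC[0-9]*$", tag)) {
    return("system")
  }
  switch(tag,
    INC = "search-path",
    UNAME = "system",
    INTERP = , INTERPVer = , INTERPSum = , LIBC = , LIBCSum = "interpreter",
    User = , Group = "user",
    ProgDir = , Program = , Version = , ProgSUM = "program",
    Args = "args",
    EndStat = "exit-status",
    "extra"
  )
}

ri_modules_by_name <- function(doc) {
  payloads <- doc$records$payload[doc$records$tag == "MODULE"]
  mods <- lapply(payloads, function(p) {
    tryCatch(parse_module_payload(p), error = function(e) NULL)
  })
  mods <- Filter(Negate(is.null), mods)
  stats::setNames(mods, vapply(mods, function(m) m$name, character(1)))
}

#' Diff two log documents
#'
#' Compares the environments recorded in two parsed logs. `MODULE` records
#' are matched by module name (load order is environment noise): version
#' and checksum mismatches are classified `module-version` /
#' `module-checksum`, unmatched names `module-added` / `module-removed`.
#' All other tags are compared literally, with repeated tags (`INC`,
#' `Group`, program-specified) compared as ordered lists. Processor
#' records are compared per index; differing processor counts additionally
#' produce one summary `system` entry. `Start`, `End` and `Elapsed` are
#' ignored by default -- timestamps always differ between runs -- while
#' `EndStat` and `Args` are compared, since differing arguments or exit
#' status plausibly explain differing results.
#'
#' @param a,b Parsed `runinfo_document` objects.
#' @param ignore Tags excluded from comparison. `"MODULE"` disables module
#'   comparison, `"PROC"` disables all processor comparison.
#' @return A `runinfo_diff`: list with `entries` (data frame with columns
#'   `category`, `tag`, `name`, `before`, `after`; `before`/`after` are
#'   `NA` only for added/removed modules) and `ignored_tags`. Zero rows
#'   means the environments are equivalent under the ignore set.
#' @export
diff_documents <- function(a, b, ignore = RI_DEFAULT_IGNORE) {
  stopifnot(inherits(a, "runinfo_document"), inherits(b, "runinfo_document"))
  cats <- character(0); tags <- character(0); names_ <- character(0)
  befores <- character(0); afters <- character(0)
  add <- function(category, tag, name = "",
                  before = NA_character_, after = NA_character_) {
    cats[[length(cats) + 1L]] <<- category
    tags[[length(tags) + 1L]] <<- tag
    names_[[length(names_) + 1L]] <<- name
    befores[[length(befores) + 1L]] <<- before
    afters[[length(afters) + 1L]] <<- after
  }
  fmt_module <- function(m) paste(m$version, m$path, m$checksum)

  if (!"MODULE" %in% ignore) {
    ma <- ri_modules_by_name(a)
    mb <- ri_modules_by_name(b)
    for (nm in sort(setdiff(names(mb), names(ma)), method = "radix")) {
      add("module-added", "MODULE", nm, NA_character_, fmt_module(mb[[nm]]))
    }
    for (nm in sort(setdiff(names(ma), names(mb)), method = "radix")) {
      add("module-removed", "MODULE", nm, fmt_module(ma[[nm]]), NA_character_)
    }
    for (nm in sort(intersect(names(ma), names(mb)), method = "radix")) {
      x <- ma[[nm]]; y <- mb[[nm]]
      if (!identical(x$version, y$version)) {
        add("module-version", "MODULE", nm, x$version, y$version)
      }
      if (!identical(x$checksum, y$checksum)) {
        add("module-checksum", "MODULE", nm, x$checksum, y$checksum)
      }
      if (!identical(x$path, y$path)) {
        add("extra", "MODULE", nm, x$path, y$path)
      }
    }
  }

  if (!identical(a$format_version, b$format_version)) {
    add("extra", "META", "format-version", a$format_version, b$format_version)
  }
  if (!identical(a$hash_algorithm, b$hash_algorithm)) {
    add("extra", "META", "hash-algorithm", a$hash_algorithm, b$hash_algorithm)
  }

  payloads_of <- function(doc, tg) doc$records$payload[doc$records$tag == tg]
  collapse <- function(x) if (length(x) == 0L) "" else paste(x, collapse = " | ")

  proc_ignored <- "PROC" %in% ignore
  proc_a <- grep("^PROC[0-9]+$", a$records$tag, value = TRUE)
  proc_b <- grep("^PROC[0-9]+$", b$records$tag, value = TRUE)
  if (!proc_ignored && length(proc_a) != length(proc_b)) {
    add("system", "PROC", "", as.character(length(proc_a)),
        as.character(length(proc_b)))
  }

  other_tags <- setdiff(union(a$records$tag, b$records$tag),
                        c("MODULE", ignore))
  if (proc_ignored) {
    other_tags <- other_tags[!grepl("^PROC[0-9]+$", other_tags)]
  }
  for (tg in sort(other_tags, method = "radix")) {
    if (grepl("^PROC[0-9]+$", tg) &&
        !(tg %in% proc_a && tg %in% proc_b)) {
      next  # count difference already reported once
    }
    la <- payloads_of(a, tg)
    lb <- payloads_of(b, tg)
    if (!identical(la, lb)) {
      add(ri_tag_diff_category(tg), tg, "", collapse(la), collapse(lb))
    }
  }

  entries <- data.frame(category = cats, tag = tags, name = names_,
                        before = befores, after = afters,
                        stringsAsFactors = FALSE)
  ord <- order(match(entries$category, RI_DIFF_CATEGORIES), entries$tag,
               entries$name, method = "radix")
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, ignored_tags = ignore),
            class = "runinfo_diff")
}

#' Summarize a diff report
#'
#' One line per entry, grouped by category in a fixed order, deterministic
#' across runs. An empty report renders as `"environments match"`.
#'
#' @param report A `runinfo_diff` from [diff_documents()].
#' @return Character vector of report lines.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "runinfo_diff"))
  e <- report$entries
  if (nrow(e) == 0L) {
    return("environments match")
  }
  side <- function(x) ifelse(is.na(x), "(absent)", x)
  sprintf("%s: %s%s: %s -> %s", e$category, e$tag,
          ifelse(nzchar(e$name), paste0(" ", e$name), ""),
          side(e$before), side(e$after))
}

#' @export
print.runinfo_diff <- function(x, ...) {
  writeLines(summarize_report(x))
  invisible(x)
}
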