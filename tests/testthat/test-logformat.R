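test_that("default log names embed program and timestamp deterministically", {
  t <- as.POSIXct("2016-06-24 10:11:12")
  expect_identical(default_log_filename("simple.pl", t),
                   "simple.pl.20160624-101112.runinfo")
  expect_identical(default_log_filename("a/b", t),
                   "a_b.20160624-101112.runinfo")
  expect_identical(default_log_filename("x", t), default_log_filename("x", t))
  expect_error(default_log_filename(""))
})

make_snapshots <- function(n_proc = 1, modules = list()) {
  list(
    modules = modules,
    search_path = snapshot_search_path(c("/lib/a", "/lib/b")),
    system = system_info("Linux", "n1", "5.10.0", "#1 SMP", "x86_64",
                         replicate(n_proc, c(model = "m", cores = "2"),
                                   simplify = FALSE), 2^30),
    interpreter = interpreter_info("/usr/bin/lang", "lang 9.9",
                                   strrep("a", 64), "glibc 2.31",
                                   strrep("b", 64)),
    user = user_context("1000(u)", c("1000(u)", "50(g)")),
    program = snapshot_program(c("in.txt", "two words"), "/w/prog.r"),
    window = finalize_window(as.POSIXct("2020-01-01", tz = "UTC"),
                             as.POSIXct("2020-01-01", tz = "UTC") + 3, 0L)
  )
}

build_from <- function(sn, extra = list()) {
  build_document(sn$modules, sn$search_path, sn$system, sn$interpreter,
                 sn$user, sn$program, sn$window, extra_records = extra)
}

test_that("build_document produces the canonical record order", {
  sn <- make_snapshots(n_proc = 3)
  doc <- build_from(sn, extra = list(log_record("SAMPLES", "42")))
  expect_length(validate_document(doc), 0)
  tags <- doc$records$tag
  # zero modules: no MODULE records, all singleton tags still present
  expect_false("MODULE" %in% tags)
  expect_identical(grep("^PROC", tags, value = TRUE),
                   c("PROC0", "PROC1", "PROC2"))
  expect_identical(tags[length(tags)], "SAMPLES")  # extras come last
  # Args payload: count, then each argument individually quoted
  expect_identical(doc$records$payload[tags == "Args"],
                   '2 "in.txt" "two words"')
})

test_that("records render as TAG: payload and wrap on continuation lines", {
  doc <- log_document(list(log_record("INTERPVer", "5.18.2")))
  expect_identical(strsplit(render_document(doc, Inf), "\n")[[1]][3],
                   "INTERPVer: 5.18.2")

  long <- paste(replicate(30, "tokenword"), collapse = " ")
  doc2 <- log_document(list(log_record("MODULE", long)))
  lines <- strsplit(render_document(doc2, 80), "\n")[[1]]
  body <- lines[-(1:2)]
  expect_gt(length(body), 1)
  expect_true(all(nchar(body) <= 80))
  expect_true(all(startsWith(body[-1], "+ ")))
  expect_identical(parse_document(lines)$records$payload, long)
})

test_that("wrapped output never exceeds the width except unbreakable tokens", {
  for (seed in 1:10) {
    doc <- ri_test_doc(seed, n_modules = 6)
    for (w in c(40, 80)) {
      lines <- strsplit(render_document(doc, w), "\n")[[1]]
      over <- lines[nchar(lines) > w]
      stripped <- sub("^\\+ ", "", sub("^[A-Za-z][A-Za-z0-9-]*: ", "", over))
      # an overlong line carries a single unbreakable segment: no isolated
      # single-space break point inside it
      expect_true(all(!grepl("(?<! ) (?! )", stripped, perl = TRUE)),
                  info = paste("width", w, "seed", seed))
    }
  }
})

test_that("parse is the inverse of render across widths", {
  for (seed in 1:40) {
    doc <- ri_test_doc(seed, n_modules = seed %% 7,
                       n_processors = 1 + seed %% 3)
    for (w in c(40, 80, Inf)) {
      expect_identical(parse_document(render_document(doc, w)), doc,
                       info = paste("seed", seed, "width", w))
    }
  }
})

test_that("parser reports orphan continuations and malformed lines by number", {
  err <- expect_error(parse_document("+ orphan"), class = "runinfo_parse_error")
  expect_match(conditionMessage(err), "line 1")
  err2 <- expect_error(parse_document(c("UNAME: ok", "no separator here")),
                       class = "runinfo_parse_error")
  expect_match(conditionMessage(err2), "line 2")
})

test_that("unknown tags are preserved, not rejected", {
  doc <- parse_document(c("META: format-version 1.0", "SAMPLES: 42"))
  expect_identical(doc$records$tag, "SAMPLES")
  expect_identical(doc$records$payload, "42")
  expect_identical(doc$format_version, "1.0")
})

test_that("MODULE payloads parse into four fields with quote handling", {
  m <- parse_module_payload("mypkg 2.1 /lib/mypkg.x UNKNOWN")
  expect_identical(m$name, "mypkg")
  expect_identical(m$version, "2.1")
  expect_identical(m$path, "/lib/mypkg.x")
  expect_identical(m$checksum, "UNKNOWN")

  rec <- module_record("p", "1.0", "/dir with space/p.x", strrep("0", 64))
  payload <- paste(rec$name, rec$version,
                   runinfo:::ri_quote_field(rec$path), rec$checksum)
  expect_identical(parse_module_payload(payload)$path, "/dir with space/p.x")

  expect_error(parse_module_payload("a b"), "4 fields")
})

test_that("write_document emits bit-exact UTF-8 with LF endings", {
  doc <- ri_test_doc(3)
  path <- file.path(withr::local_tempdir(), "x.runinfo")
  write_document(doc, path)
  bytes <- readBin(path, "raw", file.size(path))
  expect_identical(rawToChar(bytes), render_document(doc, 80))
  expect_false(as.raw(13) %in% bytes)  # no CR
  expect_identical(parse_document(readLines(path)), doc)
})

test_that("validate_document flags layout violations", {
  doc <- ri_test_doc(5)
  expect_length(validate_document(doc), 0)
  swapped <- doc
  n <- nrow(swapped$records)
  swapped$records <- swapped$records[c(n, 2:(n - 1), 1), ]
  rownames(swapped$records) <- NULL
  expect_gt(length(validate_document(swapped)), 0)
  missing_user <- doc
  missing_user$records <- missing_user$records[missing_user$records$tag != "User", ]
  expect_match(validate_document(missing_user), "User", all = FALSE)
})
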