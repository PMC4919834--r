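#' Checksum a file
#'
#' Computes the lowercase hex SHA-256 digest of a file's bytes. Capture must
#' never abort the host program, so any unreadable, missing, or non-regular
#' path yields the sentinel `"UNKNOWN"` instead of an error.
#'
#' @param path Path to a regular file.
#' @param algorithm Hash algorithm; only `"sha256"` is supported. The
#'   algorithm in force is recorded in every log's `META` header so a parser
#'   can verify digests.
#' @return A 64-character lowercase hex string, or `"UNKNOWN"`.
#' @examples
#' f <- tempfile()
#' writeLines("abc", f)
#' checksum_file(f)
#' checksum_file("/no/such/file")
#' @export
checksum_file <- function(path, algorithm = c("sha256")) {
  algorithm <- match.arg(algorithm)
  if (length(path) != 1L || is.na(path) || !nzchar(path)) {
    return(RI_UNKNOWN)
  }
  if (!file.exists(path) || dir.exists(path)) {
    return(RI_UNKNOWN)
  }
  tryCatch({
    con <- file(path, open = "rb")
    on.exit(close(con), add = TRUE)
    tolower(paste(as.character(openssl::sha256(con)), collapse = ""))
  }, error = function(e) RI_UNKNOWN)
}

is_digest_or_unknown <- function(x) {
  identical(x, RI_UNKNOWN) || grepl(sprintf("^[0-9a-f]{%d}$", RI_DIGEST_NCHAR), x)
}
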