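# Shared TSV plumbing: '#'-prefixed headers carrying the tool version and a
# parameter hash so every output file is self-describing and reruns are
# byte-comparable.

toolVersion <- function() {
  as.character(utils::packageVersion("operonclade"))
}

# 31-base polynomial rolling hash (mod 2^31 - 1) over the formatted
# parameter list; stable across sessions and platforms.
paramHash <- function(params) {
  s <- paste(names(params), vapply(params, function(x)
    paste(format(x, digits = 15), collapse = ","), ""),
    sep = "=", collapse = ";")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

fileHeader <- function(params = list(), extra = NULL) {
  c(sprintf("# operonclade %s", toolVersion()),
    if (length(params))
      sprintf("# params=%s hash=%s",
              paste(names(params), vapply(params, function(x)
                paste(format(x, digits = 15), collapse = ","), ""),
                sep = "=", collapse = ";"),
              paramHash(params)),
    if (length(extra)) paste0("# ", extra))
}

writeTsv <- function(tab, path, params = list(), header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fileHeader(params, header), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}
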