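# shared delimited-text dialect: '# key: value' header lines followed by a
# delimited numeric table (comma or tab), column names on the first
# non-comment line

read_kv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^\\s*#", lines)
  body_start <- which(!hdr & nzchar(trimws(lines)))
  if (length(body_start) == 0) stop("no data rows in ", path)
  meta <- list()
  for (ln in lines[hdr]) {
    ln <- sub("^\\s*#\\s*", "", ln)
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[seq(body_start[1], length(lines))]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  sep <- if (grepl("\t", body[1])) "\t" else if (grepl(",", body[1])) "," else ""
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  list(meta = meta, table = tab)
}

write_kv_table <- function(data, path, meta = list(), sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    val <- meta[[key]]
    writeLines(sprintf("# %s: %s", key, format(val, scientific = FALSE)), con)
  }
  utils::write.table(data, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
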