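#' Read a tab-separated table, skipping `#` comment header lines
#'
#' @param path File path.
#' @return A data.frame.
#' @keywords internal
read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table with optional `#` comment header lines
#'
#' @param x A data.frame.
#' @param path Output file path.
#' @param comments Character vector of comment lines (written as `# <line>`).
#' @return `path`, invisibly.
#' @keywords internal
write_tsv_file <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
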