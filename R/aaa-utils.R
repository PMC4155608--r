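# Shared constants and small internal helpers.

# The 20 standard one-letter amino-acid codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Full alignment alphabet: standard residues, unknown, gap.
ALN_ALPHABET <- c(AA20, "X", "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Remove gap characters from an aligned string
#' @noRd
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Validate a string over the alignment alphabet; returns the offending
#' column (first bad position) or 0 when clean.
#' @noRd
first_bad_column <- function(x) {
  cc <- chars(x)
  bad <- which(!cc %in% ALN_ALPHABET)
  if (length(bad) == 0L) 0L else bad[1L]
}

#' Stable order: ties broken by original index.
#' @noRd
stable_order <- function(w, decreasing = FALSE) {
  if (decreasing) w <- -w
  order(w, seq_along(w))
}

#' Timestamped log line on stderr, used by the CLI.
#' @noRd
ft_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Write a data.frame as TSV with a parameter-recording header comment.
#' @noRd
write_tsv_report <- function(df, path, params = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("famtrend"))
  header <- paste0("# famtrend ", version,
                   if (length(params)) paste0(" | ", paste(params, collapse = " ")))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
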