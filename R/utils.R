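# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_evhub <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_evhub(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_evhub(sprintf("`%s` must be > 0", name))
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_evhub(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# TSV conventions used throughout: tab-separated, header row, no quoting,
# UTF-8, "." decimal
read_tsv_file <- function(path, check.names = FALSE) {
  if (!file.exists(path)) stop_evhub("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = check.names,
             stringsAsFactors = FALSE, comment.char = "", quote = "")
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_evhub(sprintf("%s: required column(s) not found: %s",
                       path, paste(missing, collapse = ", ")))
  invisible(df)
}
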