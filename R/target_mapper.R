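#' Read a TargetScan-style context-score table
#'
#' Parses a TSV of predicted miRNA-target interactions carrying a cumulative
#' weighted context++ score (CWCS) per pair. Column names follow the
#' TargetScan download dialect by default and are configurable, so any
#' tabular prediction source can be consumed. Duplicate (miRNA, gene) rows
#' (e.g. one per transcript) are aggregated to the most negative — i.e.
#' strongest predicted repression — score. Identifiers are whitespace-trimmed
#' and matched case-sensitively.
#'
#' @param path TSV file path.
#' @param cols named character vector mapping the internal fields
#'   `mirna`, `gene`, `cwcs` to the file's column names.
#' @return data.frame with columns `mirna`, `gene`, `cwcs` (one row per
#'   pair).
#' @export
read_targetscan <- function(path,
                            cols = c(mirna = "miRNA",
                                     gene = "Gene Symbol",
                                     cwcs = "Cumulative weighted context++ score")) {
  df <- read_tsv_file(path)
  require_columns(df, unname(cols[c("mirna", "gene", "cwcs")]), path)
  rec <- data.frame(mirna = trimws(as.character(df[[cols[["mirna"]]]])),
                    gene = trimws(as.character(df[[cols[["gene"]]]])),
                    cwcs = as.numeric(df[[cols[["cwcs"]]]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(rec$cwcs)))
    stop_evhub(path, ": non-numeric or non-finite context score(s)")
  aggregate_targets(rec)
}

# most-negative score per (miRNA, gene) pair
aggregate_targets <- function(rec) {
  key <- paste(rec$mirna, rec$gene, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(rec$cwcs, key, min)
    first <- !duplicated(key)
    rec <- rec[first, , drop = FALSE]
    rec$cwcs <- unname(agg[paste(rec$mirna, rec$gene, sep = "\r")])
  }
  rec <- rec[order(rec$mirna, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' @rdname read_targetscan
#' @param records a target-record data.frame (`mirna`, `gene`, `cwcs`).
#' @export
write_targetscan <- function(records, path,
                             cols = c(mirna = "miRNA",
                                      gene = "Gene Symbol",
                                      cwcs = "Cumulative weighted context++ score")) {
  require_columns(records, c("mirna", "gene", "cwcs"), "records")
  out <- data.frame(records$gene, records$mirna, records$cwcs,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- cols[c("gene", "mirna", "cwcs")]
  write_tsv_file(out, path)
}

#' Filter target records on context score
#'
#' Keeps predicted targets at or below the CWCS threshold (more negative =
#' stronger predicted knockdown). The default threshold -0.4 corresponds to
#' a predicted repression of about 24% (`1 - 2^-0.4`). The threshold is
#' inclusive by default; `inclusive = FALSE` applies a strict `<`.
#'
#' @param records target-record data.frame.
#' @param cwcs_max score threshold, <= 0.
#' @param inclusive keep records equal to the threshold?
#' @return the filtered records.
#' @export
filter_targets <- function(records, cwcs_max = -0.4, inclusive = TRUE) {
  require_columns(records, c("mirna", "gene", "cwcs"), "records")
  assert_scalar_number(cwcs_max, "cwcs_max")
  if (cwcs_max > 0) stop_evhub("`cwcs_max` must be <= 0")
  keep <- if (inclusive) records$cwcs <= cwcs_max else records$cwcs < cwcs_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-direction target-gene unions for one comparison
#'
#' For the miRNAs selected by [select_top_mirnas()], collects each miRNA's
#' (score-filtered) target genes and forms the union per direction group.
#' The comparison total is reported as |up-union| + |down-union|, i.e. the
#' direction subtotals are added rather than union-ed across directions —
#' the bookkeeping a per-group target count table uses.
#'
#' @param selection data.frame with `mirna` and `direction` (`up`/`down`),
#'   as produced by [select_top_mirnas()].
#' @param records filtered target records (`mirna`, `gene`, `cwcs`).
#' @param comparison label for the comparison (e.g. `"NanogF10_vs_F10"`).
#' @return an object of class `target_map` with fields `comparison`,
#'   `selection`, `per_mirna` (named list of gene sets), `groups`
#'   (`up`/`down` union gene sets), `records` (records restricted to the
#'   selected miRNAs) and `counts` (per-miRNA sizes, group sizes, `total`).
#' @export
build_target_map <- function(selection, records, comparison = "comparison") {
  require_columns(selection, c("mirna", "direction"), "selection")
  require_columns(records, c("mirna", "gene", "cwcs"), "records")
  if (!all(selection$direction %in% c("up", "down")))
    stop_evhub("selection directions must be 'up' or 'down'")
  absent <- setdiff(selection$mirna, records$mirna)
  if (length(absent))
    warning("selected miRNA(s) absent from target records (empty set used): ",
            paste(absent, collapse = ", "))
  rec <- records[records$mirna %in% selection$mirna, , drop = FALSE]
  per_mirna <- lapply(setNames(selection$mirna, selection$mirna), function(m)
    sort(unique(rec$gene[rec$mirna == m])))
  union_of <- function(dir)
    sort(unique(unlist(per_mirna[selection$mirna[selection$direction == dir]],
                       use.names = FALSE)))
  groups <- list(up = union_of("up"), down = union_of("down"))
  counts <- list(per_mirna = vapply(per_mirna, length, integer(1)),
                 up = length(groups$up), down = length(groups$down),
                 total = length(groups$up) + length(groups$down))
  structure(list(comparison = comparison, selection = selection,
                 per_mirna = per_mirna, groups = groups, records = rec,
                 counts = counts),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> %s: %d miRNA(s); union sizes up=%d down=%d total=%d\n",
              x$comparison, length(x$per_mirna),
              x$counts$up, x$counts$down, x$counts$total))
  invisible(x)
}
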