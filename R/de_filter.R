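#' Per-miRNA differential statistics
#'
#' Computes, for every miRNA, the log2 fold change of condition B over
#' condition A on counts-per-million (CPM) scale and a two-tailed Welch
#' t-test p-value on `log2(CPM + pseudocount)`. This is the package's
#' documented differential statistic; externally computed `(log2fc, p)`
#' tables (e.g. from a vendor pipeline) can be supplied directly to
#' [classify_mirnas()] instead.
#'
#' `log2fc = log2((mean CPM_B + pseudocount) / (mean CPM_A + pseudocount))`.
#' A group with fewer than two samples yields `NA` p-values (the fold
#' change is still reported); a zero-variance miRNA yields p = 1 when the
#' group means agree and p = 0 otherwise.
#'
#' @param x an [expression_matrix()], or a count matrix if `groups` is given.
#' @param pseudocount positive stabilising offset on CPM scale.
#' @param groups named `A`/`B` vector over samples, when `x` is a bare matrix.
#' @return data.frame with columns `mirna`, `log2fc`, `p`.
#' @export
compute_mirna_stats <- function(x, pseudocount = 0.5, groups = NULL) {
  if (inherits(x, "expression_matrix")) {
    counts <- x$counts; groups <- x$groups
  } else {
    counts <- as.matrix(x)
    if (is.null(groups)) stop_evhub("`groups` required when `x` is a matrix")
    groups <- groups[colnames(counts)]
  }
  assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount < 0) stop_evhub("`pseudocount` must be >= 0")
  if (any(counts < 0)) stop_evhub("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop_evhub("sample(s) with zero library size")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  ia <- which(groups == "A"); ib <- which(groups == "B")
  if (!length(ia) || !length(ib)) stop_evhub("both groups must be present")
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  p <- rep(NA_real_, nrow(counts))
  na <- length(ia); nb <- length(ib)
  if (na >= 2L && nb >= 2L) {
    la <- log2(cpm[, ia, drop = FALSE] + pseudocount)
    lb <- log2(cpm[, ib, drop = FALSE] + pseudocount)
    ma <- rowMeans(la); mb <- rowMeans(lb)
    va <- rowSums((la - ma)^2) / (na - 1)
    vb <- rowSums((lb - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    diff <- mb - ma
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(tstat), df)
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(diff[degenerate] == 0, 1, 0)
  } else {
    warning("a group has fewer than 2 samples; p-values reported as NA")
  }
  data.frame(mirna = rownames(counts) %||% sim_mirna_ids(nrow(counts)),
             log2fc = unname(log2fc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Volcano classification of miRNAs
#'
#' Applies the joint fold-change / significance filter: `up` when
#' `log2fc > log2(fc_thresh)` and `p < p_thresh`, `down` symmetrically for
#' `log2fc < -log2(fc_thresh)`, otherwise `ns`. Raw p-values are filtered by
#' default; `adjust = "BH"` applies Benjamini-Hochberg first and filters on
#' the adjusted values.
#'
#' @param stats data.frame with at least `mirna`, `log2fc`, `p`.
#' @param fc_thresh fold-change threshold (> 0), on natural (not log) scale.
#' @param p_thresh significance threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `stats` with a `direction` column (`up`/`down`/`ns`).
#' @export
classify_mirnas <- function(stats, fc_thresh = 2, p_thresh = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  require_columns(stats, c("mirna", "log2fc", "p"), "stats")
  assert_scalar_number(fc_thresh, "fc_thresh", positive = TRUE)
  assert_scalar_number(p_thresh, "p_thresh", positive = TRUE)
  p_use <- if (adjust == "BH") p.adjust(stats$p, "BH") else stats$p
  lt <- log2(fc_thresh)
  sig <- !is.na(p_use) & p_use < p_thresh
  stats$direction <- ifelse(sig & stats$log2fc > lt, "up",
                            ifelse(sig & stats$log2fc < -lt, "down", "ns"))
  stats
}

#' Select the top differentially loaded miRNAs per direction
#'
#' Within the `up` class, takes up to `k_per_direction` miRNAs in descending
#' order of log2 fold change; within the `down` class, in descending order
#' of |log2 fold change|. Ties break lexicographically by miRNA id. Fewer
#' significant miRNAs than `k_per_direction` simply yields a shorter list.
#'
#' @param classified output of [classify_mirnas()].
#' @param k_per_direction maximum selections per direction.
#' @return data.frame of selected rows, `up` block first, each block in
#'   rank order.
#' @export
select_top_mirnas <- function(classified, k_per_direction = 4L) {
  require_columns(classified, c("mirna", "log2fc", "direction"), "classified")
  k <- assert_count(k_per_direction, "k_per_direction")
  pick <- function(dir) {
    d <- classified[classified$direction == dir, , drop = FALSE]
    ord <- order(-abs(d$log2fc), d$mirna)
    head(d[ord, , drop = FALSE], k)
  }
  out <- rbind(pick("up"), pick("down"))
  rownames(out) <- NULL
  out
}

#' Read / write per-miRNA statistics tables
#'
#' TSV with columns `mirna`, `log2fc`, `p` and optionally `direction`.
#'
#' @param path file path.
#' @return [read_stats()] returns the stats data.frame.
#' @export
read_stats <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("mirna", "log2fc", "p"), path)
  df$mirna <- trimws(as.character(df$mirna))
  df
}

#' @rdname read_stats
#' @param stats a stats data.frame.
#' @export
write_stats <- function(stats, path) {
  require_columns(stats, c("mirna", "log2fc", "p"), "stats")
  write_tsv_file(stats, path)
}
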